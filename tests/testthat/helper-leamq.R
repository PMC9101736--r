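# shared fixtures, built in code

## minimal two-section key: section A plain, section B with one
## reverse-coded item
mini_key <- function() {
  as_scoring_key(data.frame(
    item_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    section = c(rep("dizziness", 3), rep("wellbeing", 3)),
    subscale = NA_character_,
    max_code = 3L,
    reverse = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    version = "both",
    ehmc = FALSE,
    stringsAsFactors = FALSE))
}

## a complete random v2 response for the default key
random_answers <- function(key = default_scoring_key()) {
  scored <- key[key$section != "demographics" &
                  key$version %in% c("both", "v2"), ]
  ans <- lapply(scored$max_code, function(m) sample(0:m, 1))
  names(ans) <- scored$item_id
  ans
}

## independent brute-force oracle for the case/control/excluded rule,
## written directly from the verbal definition over status strings
classify_oracle <- function(statuses) {
  prim <- statuses[1:4]; all10 <- statuses
  if (sum(all10 == "missing") >= 3 && sum(prim == "missing") >= 1) {
    return("excluded")
  }
  if (sum(prim == "met") >= 2 || sum(all10 == "met") >= 3) return("case")
  "control"
}

profile_row <- function(statuses) {
  stats::setNames(as.data.frame(as.list(statuses), stringsAsFactors = FALSE),
                  c(primary_indicators(), secondary_indicators()))
}

## independent exhaustive ROC oracle: scan every candidate threshold with
## the same tie-break (max J, then max spec, then min thr), on exact
## integer counts
roc_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  u <- sort(unique(scores))
  thr <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (t in thr) {
    tp <- sum(scores > t & labels)
    tn <- sum(scores <= t & !labels)
    cand <- list(jint = tp * nn + tn * np, tn = tn, thr = t,
                 j = tp / np + tn / nn - 1, sens = tp / np)
    if (is.null(best) || cand$jint > best$jint ||
        (cand$jint == best$jint &&
         (cand$tn > best$tn ||
          (cand$tn == best$tn && cand$thr < best$thr)))) {
      best <- cand
    }
  }
  best
}

## bisection solver for the free-testosterone mass-action system
bisect_free_t <- function(tt_nmol, shbg_nmol, alb_gL = 43) {
  TT <- tt_nmol * 1e-9; SHBG <- shbg_nmol * 1e-9
  Ka <- 3.6e4; Kt <- 1e9; Ca <- alb_gL / 69000
  total_at <- function(ft) ft * (1 + Ka * Ca) + Kt * ft * SHBG / (1 + Kt * ft)
  lo <- 0; hi <- TT
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (total_at(mid) > TT) hi <- mid else lo <- mid
  }
  (lo + hi) / 2 * 1e12
}

## two-way ANOVA ICC(3,1) computed from explicit sums of squares
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m); G <- mean(m)
  SSR <- k * sum((rowMeans(m) - G)^2)
  SSC <- n * sum((colMeans(m) - G)^2)
  SSE <- sum((m - G)^2) - SSR - SSC
  MSR <- SSR / (n - 1); MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE)
}
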