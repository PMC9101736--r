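#' Score one questionnaire response
#'
#' Sums (reverse-adjusted) ordinal item codes into section scores, wellbeing
#' subscale scores, the total score, and the composite scores used in the
#' validation pipeline: the EHMC score, the low-sex-drive score and flag,
#' and weight flux. Every item is scored so that a higher value indicates a
#' greater likelihood of low energy availability.
#'
#' Section sums are computed over answered items only; a section whose
#' items are all missing (or structurally absent from the response's
#' questionnaire version) yields `NA`, not zero. No imputation or proration
#' is applied; per-section completeness fractions are returned alongside.
#'
#' @param answers named list or named vector of ordinal codes; names are
#'   `item_id`s from the key. Missing items may be absent or `NA`.
#' @param key a scoring key (see [default_scoring_key()]).
#' @param version questionnaire version of this response, `"v1"` or `"v2"`.
#' @param highest_weight_kg,lowest_weight_kg self-reported extreme body
#'   weights at current height (kg), used for weight flux; optional.
#' @return a one-row data frame with section scores (`dizziness`,
#'   `gastrointestinal`, `thermoregulation`, `injury_illness`, `wellbeing`,
#'   `sex_drive`), wellbeing subscales (`fatigue`, `poor_recovery`,
#'   `low_energy`), `total`, `ehmc_score`, `low_sex_drive_score`,
#'   `low_sex_drive_flag`, `weight_flux_kg` and `completeness`.
#' @examples
#' key <- default_scoring_key()
#' score_response(list(d01 = 1, d02 = 0, s6a = 2, s6c = 1, s6d = 0),
#'                key, version = "v2")
#' @seealso [score_responses()] for a whole cohort table.
#' @export
score_response <- function(answers, key, version = c("v2", "v1"),
                           highest_weight_kg = NA_real_,
                           lowest_weight_kg = NA_real_) {
  key <- as_scoring_key(key)
  version <- match.arg(version)
  vkey <- key_for_version(key, version)
  scored_key <- vkey[vkey$section != "demographics", , drop = FALSE]

  answers <- unlist(answers)
  if (length(answers) && is.null(names(answers))) {
    stop_schema("answers must be named by item_id")
  }
  answers <- answers[!is.na(answers)]

  unknown <- setdiff(names(answers), vkey$item_id)
  if (length(unknown)) {
    stop_schema("item(s) not in the ", version, " scoring key: ",
                paste(unknown, collapse = ", "))
  }

  idx <- match(names(answers), scored_key$item_id)
  keep <- !is.na(idx)              # demographic answers are not scored
  codes <- as.numeric(answers[keep])
  items <- scored_key[idx[keep], , drop = FALSE]
  bad <- codes %% 1 != 0 | codes < 0 | codes > items$max_code
  if (any(bad)) {
    stop_schema("code outside allowed range for item(s): ",
                paste(sprintf("%s=%s (allowed 0..%d)",
                              items$item_id[bad], codes[bad],
                              items$max_code[bad]), collapse = ", "))
  }

  ## delegate to the vectorised cohort scorer on a one-row table
  row <- data.frame(athlete_id = "x", version = version,
                    highest_weight_kg = highest_weight_kg,
                    lowest_weight_kg = lowest_weight_kg,
                    stringsAsFactors = FALSE)
  for (i in seq_along(codes)) row[[items$item_id[i]]] <- codes[i]
  out <- score_responses(row, key)
  # weight flux via the dedicated op so its validation semantics apply
  out$weight_flux_kg <- compute_weight_flux(highest_weight_kg,
                                            lowest_weight_kg)
  out <- out[, !(names(out) %in% c("athlete_id", "version")), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score a cohort of questionnaire responses
#'
#' @param responses a data frame with one row per athlete: columns
#'   `athlete_id`, `version`, optional `highest_weight_kg` /
#'   `lowest_weight_kg`, and one column per answered item (missing cells
#'   `NA`). See [read_responses()].
#' @param key a scoring key.
#' @return a data frame of per-athlete scores, one row per input row,
#'   keyed by `athlete_id`.
#' @export
score_responses <- function(responses, key = default_scoring_key()) {
  key <- as_scoring_key(key)
  scored_key <- key[key$section != "demographics", , drop = FALSE]
  n <- nrow(responses)
  if (!n) {
    out <- score_response(list(), key, version = "v2")[0, , drop = FALSE]
    return(cbind(data.frame(athlete_id = character(0),
                            version = character(0)), out))
  }
  version <- as.character(responses$version)
  if (!all(version %in% c("v1", "v2"))) {
    stop_schema("version must be 'v1' or 'v2'")
  }

  ## adjusted answer matrix, athletes x scored items (absent columns all-NA)
  adj <- matrix(NA_real_, n, nrow(scored_key),
                dimnames = list(NULL, scored_key$item_id))
  for (j in seq_len(nrow(scored_key))) {
    it <- scored_key[j, ]
    if (!it$item_id %in% names(responses)) next
    v <- as.numeric(responses[[it$item_id]])
    bad <- !is.na(v) & (v < 0 | v > it$max_code | v %% 1 != 0)
    if (any(bad)) {
      stop_schema("code outside allowed range 0..", it$max_code,
                  " for item ", it$item_id)
    }
    ## answers to items not on the athlete's questionnaire version
    answered_off_version <- !is.na(v) &
      !(it$version == "both" | it$version == version)
    if (any(answered_off_version)) {
      stop_schema("item ", it$item_id, " answered on a ",
                  paste(unique(version[answered_off_version]), collapse = "/"),
                  " response but belongs to version ", it$version)
    }
    adj[, j] <- if (it$reverse) it$max_code - v else v
  }

  nasum <- function(cols) {
    if (!length(cols)) return(rep(NA_real_, n))
    m <- adj[, cols, drop = FALSE]
    s <- rowSums(m, na.rm = TRUE)
    s[rowSums(!is.na(m)) == 0] <- NA_real_
    s
  }
  sections <- c("dizziness", "gastrointestinal", "thermoregulation",
                "injury_illness", "wellbeing", "sex_drive")
  sec <- vapply(sections, function(s)
    nasum(scored_key$item_id[scored_key$section == s]), numeric(n))
  sub <- vapply(c("fatigue", "poor_recovery", "low_energy"), function(s)
    nasum(scored_key$item_id[!is.na(scored_key$subscale) &
                               scored_key$subscale == s]), numeric(n))
  if (n == 1) { sec <- t(sec); sub <- t(sub) }
  total <- rowSums(sec, na.rm = TRUE)
  total[rowSums(!is.na(sec)) == 0] <- NA_real_

  ehmc_ids <- scored_key$item_id[scored_key$ehmc]
  ehmc <- rowSums(adj[, ehmc_ids, drop = FALSE])   # NA unless all present

  g <- function(id) if (id %in% colnames(adj)) adj[, id] else
    rep(NA_real_, n)
  lsd <- g("s6a") >= 2 | (g("s6c") >= 2 & g("s6d") >= 1)
  ## all three items are required: any missing -> flag missing
  lsd[is.na(g("s6a")) | is.na(g("s6c")) | is.na(g("s6d"))] <- NA
  lsd[version == "v1"] <- NA

  hw <- as.numeric(responses$highest_weight_kg %||% rep(NA_real_, n))
  lw <- as.numeric(responses$lowest_weight_kg %||% rep(NA_real_, n))
  swapped <- !is.na(hw) & !is.na(lw) & hw < lw
  if (any(swapped)) {
    stop_schema("highest weight below lowest weight for athlete(s): ",
                paste(responses$athlete_id[swapped], collapse = ", "))
  }
  flux <- hw - lw

  cbind(data.frame(athlete_id = responses$athlete_id, version = version,
                   stringsAsFactors = FALSE),
        as.data.frame(sec), as.data.frame(sub),
        data.frame(total = total, ehmc_score = ehmc,
                   low_sex_drive_score = sec[, "sex_drive"],
                   low_sex_drive_flag = lsd, weight_flux_kg = flux,
                   completeness = rowSums(!is.na(adj)) / ncol(adj)))
}

#' Weight flux from self-reported extreme weights
#'
#' The difference between the self-reported highest and lowest body weight
#' at current height. Uses the questionnaire responses, not measured body
#' mass.
#'
#' @param highest_kg,lowest_kg weights in kg.
#' @return `highest_kg - lowest_kg`, or `NA` if either is missing.
#' @export
compute_weight_flux <- function(highest_kg, lowest_kg) {
  if (is_missing(highest_kg) || is_missing(lowest_kg)) return(NA_real_)
  if (highest_kg < lowest_kg) {
    stop_schema("highest weight (", highest_kg, ") below lowest weight (",
                lowest_kg, "): likely data-entry swap")
  }
  highest_kg - lowest_kg
}

#' Categorise low sex drive from the sex-drive items
#'
#' An athlete is flagged as having a low sex drive when the general
#' sex-drive rating is 2 or more, or when the morning-erection frequency
#' item is 2 or more together with a morning-erections-compared-to-normal
#' item of 1 or more. Requires the version-2 items `s6a`, `s6c`, `s6d`;
#' on a version-1 response the flag is `NA` with a warning.
#'
#' @param s6a,s6c,s6d ordinal codes of the three required sex-drive items
#'   (general sex drive, morning-erection frequency, morning erections
#'   compared to normal).
#' @param version questionnaire version of the response.
#' @return logical: `TRUE`/`FALSE`, or `NA` where a required item is
#'   missing or the response is version 1.
#' @export
categorize_low_sex_drive <- function(s6a, s6c, s6d, version = "v2") {
  if (version == "v1") {
    warning("low sex drive cannot be categorised on a version-1 response",
            call. = FALSE)
    return(NA)
  }
  low_sex_drive_rule(s6a, s6c, s6d)
}

low_sex_drive_rule <- function(s6a, s6c, s6d) {
  if (is.na(s6a) || is.na(s6c) || is.na(s6d)) return(NA)
  (s6a >= 2) || (s6c >= 2 && s6d >= 1)
}

#' EHMC composite score
#'
#' Sum of the nine items screening for the Exercise Hypogonadal Male
#' Condition: the three sex-drive items (general sex drive, morning
#' erections over the last month, morning erections compared to normal)
#' and six wellbeing items (tiredness, lethargy and the reverse-coded
#' strength-progress, energy, invigoration and happiness items). Missing
#' if any constituent is unanswered.
#'
#' @inheritParams score_response
#' @return integer score, or `NA` when any constituent item is missing.
#' @export
compute_ehmc_score <- function(answers, key = default_scoring_key(),
                               version = "v2") {
  score_response(answers, key, version = version)$ehmc_score
}
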