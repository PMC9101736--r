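`%||%` <- function(a, b) if (is.null(a)) b else a

## condition constructors: schema errors (exit code 2 at the CLI) and
## configuration errors (exit code 3) are distinguishable by class
stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("leamq_schema_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("leamq_config_error", "error")))
}

is_missing <- function(x) is.null(x) || length(x) == 0 || all(is.na(x))

## strict "value below cutoff" respecting missingness: NA in -> NA out
lt <- function(x, cutoff) ifelse(is.na(x), NA, x < cutoff)
gt <- function(x, cutoff) ifelse(is.na(x), NA, x > cutoff)

## disjunction over indicator branches where an unavailable branch does not
## veto the available one: TRUE if any branch TRUE; FALSE if any branch is
## known FALSE and none TRUE; NA only when every branch is NA
or_lenient <- function(...) {
  b <- c(...)
  if (any(b %in% TRUE)) return(TRUE)
  if (all(is.na(b))) return(NA)
  FALSE
}

## md5 of an R object via its canonical JSON serialisation (for manifests)
object_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                           force = TRUE)), tf)
  unname(tools::md5sum(tf))
}
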