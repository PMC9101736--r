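#' Scoring keys for the LEAM-Q questionnaire
#'
#' A scoring key is a data frame with one row per questionnaire item and
#' columns:
#' \describe{
#'   \item{item_id}{unique item identifier, e.g. `"s6a"`.}
#'   \item{label}{short human-readable item text.}
#'   \item{section}{one of `"dizziness"`, `"gastrointestinal"`,
#'     `"thermoregulation"`, `"injury_illness"`, `"wellbeing"`,
#'     `"sex_drive"`, `"demographics"`.}
#'   \item{subscale}{optional wellbeing subscale (`"fatigue"`,
#'     `"poor_recovery"`, `"low_energy"`) or `NA`.}
#'   \item{max_code}{largest allowed ordinal code; allowed codes are the
#'     integers `0:max_code`. `NA` for unscored demographic items.}
#'   \item{reverse}{logical; `TRUE` for positively worded items whose code
#'     is replaced by `max_code - code` before summation, so that a higher
#'     score always indicates a greater likelihood of low energy
#'     availability.}
#'   \item{version}{questionnaire version availability: `"v1"`, `"v2"` or
#'     `"both"`. Version 1 carried 33 items; the revision added sex drive
#'     and further dizziness/wellbeing items for a total of 42.}
#'   \item{ehmc}{logical; item contributes to the Exercise Hypogonadal Male
#'     Condition (EHMC) composite score.}
#' }
#'
#' @section Default key:
#' The exact wording and response options of the instrument are a
#' configuration concern; `default_scoring_key()` ships the section
#' structure used throughout the package (ordinal codes 0--3 per item,
#' positively worded wellbeing items reverse-coded) so that scoring,
#' simulation and the validation pipeline agree on one canonical layout.
#'
#' @return `default_scoring_key()` returns a validated scoring-key data
#'   frame of class `leamq_key`.
#' @examples
#' key <- default_scoring_key()
#' table(key$section, key$version)
#' @export
default_scoring_key <- function() {
  row <- function(item_id, label, section, subscale = NA_character_,
                  max_code = 3L, reverse = FALSE, version = "both",
                  ehmc = FALSE) {
    data.frame(item_id = item_id, label = label, section = section,
               subscale = subscale, max_code = max_code, reverse = reverse,
               version = version, ehmc = ehmc, stringsAsFactors = FALSE)
  }
  key <- rbind(
    ## Section 1: dizziness
    row("d01", "Dizziness during training", "dizziness"),
    row("d02", "Dizziness outside training", "dizziness"),
    row("d03", "Dizziness when standing up quickly", "dizziness",
        version = "v2"),
    ## Section 2: gastrointestinal
    row("g01", "Bloating or cramps", "gastrointestinal"),
    row("g02", "Bowel movement frequency", "gastrointestinal"),
    row("g03", "How would you describe your normal stool", "gastrointestinal"),
    ## Section 3: thermoregulation
    row("t01", "Feeling cold when others are comfortable", "thermoregulation"),
    row("t02", "Needing extra layers during training", "thermoregulation"),
    row("t03", "Cold hands and feet", "thermoregulation"),
    ## Section 4: injury and illness
    row("i4a", "How many acute injuries", "injury_illness"),
    row("i4b", "How many overload injuries", "injury_illness"),
    row("i4c", "Breaks in training for overload injury", "injury_illness"),
    row("i4d", "Breaks in training for acute injury", "injury_illness"),
    row("i4e", "Number of illness episodes", "injury_illness"),
    row("i4f", "Days unable to train due to illness", "injury_illness"),
    ## Section 5: wellbeing and recovery
    row("w01", "I feel tired from work or school", "wellbeing",
        subscale = "fatigue", ehmc = TRUE),
    row("w02", "I feel lethargic", "wellbeing",
        subscale = "fatigue", ehmc = TRUE),
    row("w03", "I feel worn out during the day", "wellbeing",
        subscale = "fatigue"),
    row("w04", "My muscles feel heavy in training", "wellbeing",
        subscale = "poor_recovery"),
    row("w05", "I recover slowly between sessions", "wellbeing",
        subscale = "poor_recovery"),
    row("w06", "I feel sore for longer than usual", "wellbeing",
        subscale = "poor_recovery"),
    row("w07", "I feel very energetic in general", "wellbeing",
        subscale = "low_energy", reverse = TRUE, ehmc = TRUE),
    row("w08", "My energy levels are low", "wellbeing",
        subscale = "low_energy"),
    row("w12", "I feel down and less happy than I used to feel", "wellbeing"),
    row("w09", "I feel strong and making good progress with strength training",
        "wellbeing", reverse = TRUE, version = "v2", ehmc = TRUE),
    row("w10", "I feel invigorated for training and ready to perform well",
        "wellbeing", reverse = TRUE, version = "v2", ehmc = TRUE),
    row("w11", "I feel happy and on top of my life outside of sport",
        "wellbeing", reverse = TRUE, version = "v2", ehmc = TRUE),
    row("w13", "I sleep poorly before or after training", "wellbeing",
        version = "v2"),
    ## Section 6: sex drive (version 2 only)
    row("s6a", "How would you rate your sex drive in general", "sex_drive",
        version = "v2", ehmc = TRUE),
    row("s6b", "Sex drive over the last month compared to normal",
        "sex_drive", version = "v2"),
    row("s6c", "How often would you wake with a morning erection",
        "sex_drive", version = "v2", ehmc = TRUE),
    row("s6d", "Number of morning erections compared to normal", "sex_drive",
        version = "v2", ehmc = TRUE),
    ## Demographic / athletic status items (not scored)
    row(sprintf("dem%02d", 1:10),
        c("Age", "Sport", "Competition level", "Training hours per week",
          "Years in sport", "Full-time athlete", "Country",
          "Highest body weight at current height",
          "Lowest body weight at current height", "Current body weight"),
        "demographics", max_code = NA_integer_)
  )
  as_scoring_key(key)
}

#' Validate a scoring-key data frame
#'
#' Checks key invariants (unique item ids, known sections, non-empty
#' allowed-code sets for scored items, valid version tags) and returns the
#' key with class `leamq_key`.
#'
#' @param key a data frame with the columns described in
#'   [default_scoring_key()].
#' @return the validated key, classed `leamq_key`.
#' @export
as_scoring_key <- function(key) {
  needed <- c("item_id", "section", "max_code", "reverse", "version")
  missing_cols <- setdiff(needed, names(key))
  if (length(missing_cols)) {
    stop_schema("scoring key is missing columns: ",
                paste(missing_cols, collapse = ", "))
  }
  if (is.null(key$subscale)) key$subscale <- NA_character_
  if (is.null(key$ehmc)) key$ehmc <- FALSE
  if (is.null(key$label)) key$label <- key$item_id
  if (anyDuplicated(key$item_id)) {
    stop_schema("duplicated item_id in scoring key: ",
                paste(unique(key$item_id[duplicated(key$item_id)]),
                      collapse = ", "))
  }
  sections <- c("dizziness", "gastrointestinal", "thermoregulation",
                "injury_illness", "wellbeing", "sex_drive", "demographics")
  bad <- setdiff(unique(key$section), sections)
  if (length(bad)) stop_schema("unknown section(s): ", paste(bad, collapse = ", "))
  if (!all(key$version %in% c("v1", "v2", "both"))) {
    stop_schema("version must be one of 'v1', 'v2', 'both'")
  }
  scored <- key$section != "demographics"
  if (any(scored & (is.na(key$max_code) | key$max_code < 1))) {
    stop_schema("every scored item needs max_code >= 1")
  }
  key$max_code <- as.integer(key$max_code)
  key$reverse <- as.logical(key$reverse)
  key$ehmc <- as.logical(key$ehmc)
  class(key) <- c("leamq_key", "data.frame")
  key
}

#' @rdname as_scoring_key
#' @param version `"v1"` or `"v2"`: restrict a key to the items available
#'   on one questionnaire version.
#' @export
key_for_version <- function(key, version) {
  version <- match.arg(version, c("v1", "v2"))
  key[key$version %in% c("both", version), , drop = FALSE]
}

#' Read or write a scoring key as YAML
#'
#' The on-disk format is a YAML list with one entry per item carrying the
#' columns of [default_scoring_key()].
#'
#' @param path file path.
#' @return `read_scoring_key()` returns a validated `leamq_key`.
#' @export
read_scoring_key <- function(path) {
  if (!file.exists(path)) stop_config("scoring key file not found: ", path)
  raw <- yaml::read_yaml(path)
  key <- do.call(rbind, lapply(raw, function(x) {
    data.frame(item_id = x$item_id,
               label = x$label %||% x$item_id,
               section = x$section,
               subscale = x$subscale %||% NA_character_,
               max_code = x$max_code %||% NA_integer_,
               reverse = isTRUE(x$reverse),
               version = x$version %||% "both",
               ehmc = isTRUE(x$ehmc),
               stringsAsFactors = FALSE)
  }))
  as_scoring_key(key)
}

#' @rdname read_scoring_key
#' @param key a `leamq_key`.
#' @export
write_scoring_key <- function(key, path) {
  key <- as_scoring_key(key)
  entries <- lapply(seq_len(nrow(key)), function(i) {
    x <- as.list(key[i, , drop = FALSE])
    x <- lapply(x, function(v) if (is.na(v)) NULL else unname(v))
    Filter(Negate(is.null), x)
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

## reverse adjustment; an involution on 0:max_code
reverse_adjust <- function(code, max_code, reverse) {
  ifelse(rep_len(reverse, length(code)), max_code - code, code)
}
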