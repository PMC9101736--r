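#' Load and validate a delimited table
#'
#' Reads a CSV with `read.csv`, then checks it against a lightweight
#' schema: required columns present, a unique non-empty id column, and
#' numeric columns actually numeric. Row- and column-level problems are
#' collected and reported together in a single schema error rather than
#' one at a time.
#'
#' @param path CSV file path (missing cells empty).
#' @param required character vector of required column names.
#' @param id_col name of the unique-id column, or `NULL` to skip the
#'   uniqueness check.
#' @param numeric_cols columns that must be numeric (coercible cells are
#'   coerced; non-numeric cells are schema errors).
#' @return the validated data frame.
#' @export
load_table <- function(path, required = character(0), id_col = NULL,
                       numeric_cols = character(0)) {
  if (!file.exists(path)) stop_schema("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  problems <- character(0)
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    problems <- c(problems,
                  paste("missing required column(s):",
                        paste(miss, collapse = ", ")))
  }
  if (!is.null(id_col) && id_col %in% names(d)) {
    ids <- d[[id_col]]
    if (anyNA(ids)) problems <- c(problems, paste("empty", id_col, "cells"))
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) {
      problems <- c(problems, paste0("duplicated ", id_col, ": ",
                                     paste(dup, collapse = ", ")))
    }
  }
  for (cl in intersect(numeric_cols, names(d))) {
    v <- d[[cl]]
    if (is.numeric(v) || all(is.na(v))) next
    coerced <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(coerced))
    if (length(bad)) {
      problems <- c(problems,
                    sprintf("non-numeric value(s) in '%s' at row(s) %s", cl,
                            paste(utils::head(bad, 5), collapse = ", ")))
    } else {
      d[[cl]] <- coerced
    }
  }
  if (length(problems)) {
    stop_schema("schema validation failed for ", path, ":\n  ",
                paste(problems, collapse = "\n  "))
  }
  d
}

#' Read a questionnaire response table
#'
#' One row per athlete; columns `athlete_id`, `version` (`v1`/`v2`),
#' optional `highest_weight_kg`/`lowest_weight_kg`, and one column per
#' item id in the scoring key. Item codes are validated against the key's
#' allowed codes for the athlete's version.
#'
#' @param path CSV path.
#' @param key scoring key used for validation.
#' @return validated response data frame.
#' @export
read_responses <- function(path, key = default_scoring_key()) {
  key <- as_scoring_key(key)
  scored <- key[key$section != "demographics", ]
  d <- load_table(path, required = c("athlete_id", "version"),
                  id_col = "athlete_id",
                  numeric_cols = c(scored$item_id, "highest_weight_kg",
                                   "lowest_weight_kg"))
  problems <- character(0)
  bad_ver <- !d$version %in% c("v1", "v2")
  if (any(bad_ver)) {
    problems <- c(problems, paste("invalid version for athlete(s):",
                                  paste(d$athlete_id[bad_ver], collapse = ", ")))
  }
  for (cl in intersect(scored$item_id, names(d))) {
    mx <- scored$max_code[scored$item_id == cl]
    v <- d[[cl]]
    bad <- !is.na(v) & (v < 0 | v > mx | v %% 1 != 0)
    if (any(bad)) {
      problems <- c(problems,
                    sprintf("item %s: code(s) outside 0..%d for athlete(s) %s",
                            cl, mx,
                            paste(d$athlete_id[bad], collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop_schema("response validation failed for ", path, ":\n  ",
                paste(problems, collapse = "\n  "))
  }
  d
}

#' Read a clinical panel table
#'
#' One row per athlete; canonical columns (units): `centre`, `age` (y),
#' `height` (cm), `body_mass` (kg), `bmi` (kg/m2), `ffm` (kg, DXA),
#' `body_fat_pct` (%), `spine_bmd_z`, `femur_bmd_z` (Z-scores),
#' `systolic_bp`, `diastolic_bp` (mmHg), `rmr_measured` (kJ/day),
#' `rmr_method` (`first_principles`/`metabolic_cart`), `glucose` (mmol/L),
#' `insulin` (pmol/L), `cortisol` (nmol/L), `total_testosterone` (nmol/L),
#' `shbg` (nmol/L), `albumin` (g/L), `free_testosterone` (pmol/L),
#' `t3` (pmol/L), `igf1` (nmol/L), `total_chol`, `ldl`, `hdl`,
#' `triglycerides` (mmol/L), `elite` (logical). Any value may be missing.
#' A consistency check flags BMI values that disagree with mass/height by
#' more than 0.1.
#'
#' @param path CSV path.
#' @return validated clinical panel data frame.
#' @export
read_clinical_panel <- function(path) {
  num <- setdiff(names(empty_clinical_table()),
                 c("athlete_id", "centre", "rmr_method", "elite"))
  d <- load_table(path, required = "athlete_id", id_col = "athlete_id",
                  numeric_cols = num)
  if (all(c("bmi", "body_mass", "height") %in% names(d))) {
    implied <- d$body_mass / (d$height / 100)^2
    off <- !is.na(d$bmi) & !is.na(implied) & abs(d$bmi - implied) >= 0.1
    if (any(off)) {
      warning("BMI inconsistent with mass/height for athlete(s): ",
              paste(d$athlete_id[off], collapse = ", "), call. = FALSE)
    }
  }
  if ("elite" %in% names(d)) d$elite <- as.logical(d$elite)
  d
}

#' Read or write a reference configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_reference_config()` returns a reference-config list in
#'   the layout of [default_reference_config()].
#' @export
read_reference_config <- function(path) {
  if (!file.exists(path)) stop_config("reference config not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (part in c("fixed", "rmr_ratio_low", "default_low")) {
    if (is.null(cfg[[part]])) {
      stop_config("reference config missing section: ", part)
    }
  }
  cfg$rmr_ratio_low <- unlist(cfg$rmr_ratio_low)
  if (!all(c("first_principles", "metabolic_cart") %in%
           names(cfg$rmr_ratio_low))) {
    stop_config("rmr_ratio_low must name both measurement methods")
  }
  cfg$centres <- lapply(cfg$centres %||% list(), function(site) {
    site$ranges <- lapply(site$ranges, function(r) {
      r <- unlist(r)
      if (length(r) != 2 || r[1] >= r[2]) {
        stop_config("reference intervals must be (low, high) with low < high")
      }
      r
    })
    if (!is.null(site$igf1_age_bands)) {
      site$igf1_age_bands <- as.data.frame(
        lapply(do.call(rbind, lapply(site$igf1_age_bands, as.data.frame)),
               as.numeric))
    }
    site
  })
  cfg
}

#' @rdname read_reference_config
#' @param ref a reference-config list.
#' @export
write_reference_config <- function(ref, path) {
  ref$rmr_ratio_low <- as.list(ref$rmr_ratio_low)
  ref$centres <- lapply(ref$centres, function(site) {
    site$ranges <- lapply(site$ranges, as.list)
    if (!is.null(site$igf1_age_bands)) {
      site$igf1_age_bands <- lapply(seq_len(nrow(site$igf1_age_bands)),
                                    function(i) as.list(site$igf1_age_bands[i, ]))
    }
    site
  })
  yaml::write_yaml(ref, path)
  invisible(path)
}

#' Write the pipeline report to disk
#'
#' Emits the association screen, the ROC table, the case-control
#' comparisons of questionnaire scores and of subject characteristics, the
#' classification with its exclusion log, and a JSON run manifest. Column
#' order is deterministic; a rerun of the same pipeline result is
#' byte-identical.
#'
#' @param results a `leamq_validation` object.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, out_dir) {
  stopifnot(inherits(results, "leamq_validation"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  paths <- c(
    associations = file.path(out_dir, "associations.csv"),
    roc = file.path(out_dir, "roc.csv"),
    score_comparisons = file.path(out_dir, "score_comparisons.csv"),
    characteristics = file.path(out_dir, "characteristics.csv"),
    classification = file.path(out_dir, "classification.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  wr <- function(df, path) utils::write.csv(df, path, row.names = FALSE,
                                            na = "")
  wr(results$associations, paths["associations"])
  wr(results$roc, paths["roc"])
  wr(results$score_comparisons, paths["score_comparisons"])
  wr(results$characteristics, paths["characteristics"])
  wr(merge(results$classification,
           results$profile %||% data.frame(athlete_id = character(0)),
           by = "athlete_id", all.x = TRUE, sort = TRUE),
     paths["classification"])
  manifest <- results$manifest
  manifest$retained <- as.list(results$retained)
  manifest$excluded_athletes <- as.list(results$exclusions$athlete_id)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
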