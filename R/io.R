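#' @keywords internal
"_PACKAGE"

# Canonical column schemas. Writers emit exactly these; readers require the
# mandatory ones and preserve (but flag) anything extra.
.participant_cols <- c(
  "subject_id", "pair_id", "status", "age", "menopausal", "er", "pr", "her2",
  "ethnicity", "income_band", "education", "smoker", "waist_cm", "height_cm",
  "weight_kg", "hiv", "pa_metric", "pa_active", "alcohol_g"
)
.participant_mandatory <- c("subject_id", "pair_id", "status", "age")
.nutrient_cols <- c("subject_id", "energy_kj", "fat_g", "sfa_g",
                    "added_sugar_g", "alcohol_g")

.status_levels <- c("case", "control")
.unknown_levels <- list(
  menopausal = c("pre", "post", "unknown"),
  er = c("positive", "negative", "unknown"),
  pr = c("positive", "negative", "unknown"),
  her2 = c("positive", "negative", "unknown"),
  hiv = c("positive", "negative", "unknown")
)

#' Construct a validated matched-study container
#'
#' Bundles the three per-subject tables of a matched case-control dietary
#' study: participant covariates, item-level daily intakes (g/d) and nutrient
#' totals. Every subject must appear in all three tables, and every pair id
#' must link exactly one case to one control.
#'
#' @param participants data.frame with one row per subject; mandatory columns
#'   `subject_id`, `pair_id`, `status` (`"case"`/`"control"`), `age`, plus the
#'   covariates documented in the package README.
#' @param intakes data.frame with `subject_id` plus one numeric column per
#'   food item holding grams/day.
#' @param nutrients data.frame with columns `subject_id`, `energy_kj`,
#'   `fat_g`, `sfa_g`, `added_sugar_g`, `alcohol_g`.
#' @param meta optional named list of provenance metadata (source path,
#'   schema version, simulation seed).
#' @return An object of class `safbdg_study`.
#' @export
safbdg_study <- function(participants, intakes, nutrients, meta = list()) {
  participants <- .normalise_participants(participants)
  stopifnot(is.data.frame(intakes), is.data.frame(nutrients))
  x <- structure(
    list(participants = participants, intakes = intakes,
         nutrients = nutrients, meta = meta),
    class = "safbdg_study"
  )
  validate_study(x)
  x
}

.normalise_participants <- function(p) {
  missing_cols <- setdiff(.participant_mandatory, names(p))
  if (length(missing_cols)) {
    stop("participant table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  p$subject_id <- as.character(p$subject_id)
  p$pair_id <- as.character(p$pair_id)
  p$status <- as.character(p$status)
  # empty cells on categorical covariates become the explicit "unknown" level
  for (col in names(.unknown_levels)) {
    if (col %in% names(p)) {
      v <- as.character(p[[col]])
      v[is.na(v) | v == ""] <- "unknown"
      p[[col]] <- v
    }
  }
  p
}

#' Validate a study container
#'
#' Checks the documented invariants: status levels, 1:1 pair completeness,
#' positive anthropometry, age over 17, one intake/nutrient row per subject,
#' positive energy and the fat >= saturated-fat ordering.
#'
#' @param x a `safbdg_study`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_study <- function(x) {
  p <- x$participants
  if (!all(p$status %in% .status_levels)) {
    stop("status must be one of 'case'/'control'", call. = FALSE)
  }
  if (anyDuplicated(p$subject_id)) {
    stop("duplicated subject_id in participant table", call. = FALSE)
  }
  tab <- table(p$pair_id, factor(p$status, .status_levels))
  bad <- rownames(tab)[tab[, "case"] != 1L | tab[, "control"] != 1L]
  if (length(bad)) {
    stop("pairing error: pair(s) without exactly one case and one control: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(p$age <= 17, na.rm = TRUE)) {
    stop("age must exceed 17 years", call. = FALSE)
  }
  for (col in c("waist_cm", "height_cm", "weight_kg")) {
    if (col %in% names(p) && any(p[[col]] <= 0, na.rm = TRUE)) {
      stop(col, " must be strictly positive when present", call. = FALSE)
    }
  }
  for (tb in c("intakes", "nutrients")) {
    ids <- x[[tb]]$subject_id
    if (!setequal(ids, p$subject_id) || anyDuplicated(ids)) {
      stop("each participant needs exactly one row in the ", tb, " table",
           call. = FALSE)
    }
  }
  item_cols <- setdiff(names(x$intakes), "subject_id")
  im <- as.matrix(x$intakes[item_cols])
  if (any(!is.finite(im)) || any(im < 0)) {
    stop("item intakes must be finite and nonnegative", call. = FALSE)
  }
  nu <- x$nutrients
  missing_cols <- setdiff(.nutrient_cols, names(nu))
  if (length(missing_cols)) {
    stop("nutrient table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(nu$energy_kj <= 0)) stop("energy_kj must be positive", call. = FALSE)
  if (any(nu$sfa_g < 0) || any(nu$fat_g < nu$sfa_g)) {
    stop("nutrients must satisfy fat_g >= sfa_g >= 0", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.safbdg_study <- function(x, ...) {
  p <- x$participants
  cat("Matched case-control dietary study\n")
  cat(sprintf("  subjects: %d (%d pairs), food items: %d\n",
              nrow(p), length(unique(p$pair_id)),
              ncol(x$intakes) - 1L))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a study from its three CSV tables
#'
#' Files are UTF-8, comma-delimited with a mandatory header row. Unknown
#' columns are preserved but reported. Row counts are reported via `message()`.
#'
#' @param participants_path,intakes_path,nutrients_path CSV paths.
#' @return A validated [safbdg_study()].
#' @export
read_study <- function(participants_path, intakes_path, nutrients_path) {
  rd <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
  }
  p <- rd(participants_path)
  extra <- setdiff(names(p), .participant_cols)
  if (length(extra)) {
    message("participant table: preserving unknown column(s): ",
            paste(extra, collapse = ", "))
  }
  x <- safbdg_study(p, rd(intakes_path), rd(nutrients_path),
                    meta = list(source = participants_path))
  message(sprintf("read %d subjects in %d pairs, %d food items",
                  nrow(x$participants),
                  length(unique(x$participants$pair_id)),
                  ncol(x$intakes) - 1L))
  x
}

#' Write a study back to the three CSV tables
#'
#' Emits the same schemas [read_study()] consumes, so
#' `read_study()` of the written files reproduces the study.
#'
#' @param x a `safbdg_study`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_study <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("participants.csv", "intakes.csv",
                            "nutrients.csv"))
  utils::write.csv(x$participants, paths[1], row.names = FALSE)
  utils::write.csv(x$intakes, paths[2], row.names = FALSE)
  utils::write.csv(x$nutrients, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Body mass index with obesity flag
#'
#' @param weight_kg,height_cm positive measured weight and height.
#' @return data.frame with `bmi` (kg/m^2) and `obese` (BMI >= 30).
#' @examples
#' compute_bmi(90, 173.1)  # obese at BMI 30.04
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0, na.rm = TRUE) || any(height_cm <= 0, na.rm = TRUE)) {
    stop("weight and height must be strictly positive", call. = FALSE)
  }
  bmi <- weight_kg / (height_cm / 100)^2
  data.frame(bmi = bmi, obese = bmi >= 30)
}
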