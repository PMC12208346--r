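#' Column contract for longitudinal sleep-affect tables
#'
#' The long-format table has one row per person-night. Required columns:
#' `id`, `day` (1-based integer), the composition in minutes (`twt_min`,
#' `light_min`, `sws_min`, `rem_min`, `tib_min`), the four morning affect
#' outcomes (`hap`, `lap`, `hana`, `lana`, each on the 1-5 scale, possibly
#' missing), the matched previous-night pre-sleep affect scores
#' (`presleep_hap`, ..., `presleep_lana`), daily covariates `weekend` (0/1)
#' and `cpd` (circadian misalignment, composite phase deviation), and
#' baseline covariates `age`, `gender`, `ethnicity`, `sss` (subjective
#' social status), `bmi`.
#'
#' @return Character vector of required column names in order.
#' @export
sleep_table_columns <- function() {
  c("id", "day",
    "twt_min", "light_min", "sws_min", "rem_min", "tib_min",
    "hap", "lap", "hana", "lana",
    "presleep_hap", "presleep_lap", "presleep_hana", "presleep_lana",
    "weekend", "cpd", "age", "gender", "ethnicity", "sss", "bmi")
}

part_cols <- function() paste0(SLEEP_PARTS, "_min")

validate_sleep_table <- function(df) {
  missing_cols <- setdiff(sleep_table_columns(), names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df[, c("id", "day")])) {
    stop("(id, day) pairs must be unique")
  }
  comp <- as.matrix(df[, part_cols()])
  obs <- stats::complete.cases(comp) & !is.na(df$tib_min)
  bad <- obs & (abs(rowSums(comp) - df$tib_min) > 1e-6)
  if (any(bad)) {
    stop("sleep stages do not sum to time in bed for ", sum(bad), " night(s)")
  }
  if (any(comp[obs, ] < 0)) stop("negative stage durations found")
  invisible(df)
}

#' Read a longitudinal sleep-affect CSV
#'
#' Reads the package's input dialect (UTF-8, header row, empty cells for
#' missing values; see [sleep_table_columns()]) and validates the
#' composition invariants: unique `(id, day)`, non-negative stage minutes
#' summing to `tib_min` within 1e-6 for every complete night.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @export
read_sleep_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  validate_sleep_table(df)
  df
}

#' Write a longitudinal sleep-affect CSV
#'
#' @param df Table following the [sleep_table_columns()] contract.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sleep_csv <- function(df, path) {
  validate_sleep_table(df)
  utils::write.csv(df[, sleep_table_columns()], path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Between-/within-person decomposition of nightly compositions
#'
#' Computes, for every complete night, the person-level ilr coordinates
#' `b` (ilr of the person's geometric-mean composition, constant within
#' person) and the within-person deviation `w = ilr(night) - b`. The sum
#' `b + w` reproduces each night's ilr coordinates exactly, and `w`
#' averages to zero within each person.
#'
#' Nights with any missing stage are dropped (listwise at the night level);
#' persons left with no complete night are dropped with a warning. Zero
#' stage durations are replaced multiplicatively before transforming.
#'
#' @param df Table per [sleep_table_columns()].
#' @param basis An `ilr_basis` (default from [default_sbp()]).
#' @param delta Zero-replacement duration in minutes (default 0.5).
#' @return A data frame: the complete-night rows of `df` plus columns
#'   `b1..b3` and `w1..w3`, with the basis attached as attribute `basis`.
#' @export
decompose_bw <- function(df, basis = build_ilr_basis(default_sbp()),
                         delta = 0.5) {
  basis <- as_ilr_basis(basis)
  validate_sleep_table(df)
  comp <- as.matrix(df[, part_cols()])
  keep <- stats::complete.cases(comp) & !is.na(df$tib_min)
  dropped_persons <- setdiff(unique(df$id), unique(df$id[keep]))
  if (length(dropped_persons)) {
    warning("dropping ", length(dropped_persons),
            " person(s) with no complete night: ",
            paste(dropped_persons, collapse = ", "))
  }
  df <- df[keep, , drop = FALSE]
  comp <- comp[keep, , drop = FALSE]
  if (!nrow(df)) stop("no complete nights available")
  comp <- t(vapply(seq_len(nrow(comp)),
                   function(i) replace_zeros(comp[i, ], df$tib_min[i], delta),
                   numeric(ncol(comp))))
  z <- ilr_transform(comp, basis)
  b <- matrix(NA_real_, nrow(z), ncol(z))
  for (pid in unique(df$id)) {
    idx <- which(df$id == pid)
    b[idx, ] <- rep(colMeans(z[idx, , drop = FALSE]), each = length(idx))
  }
  w <- z - b
  colnames(b) <- paste0("b", seq_len(ncol(b)))
  colnames(w) <- paste0("w", seq_len(ncol(w)))
  out <- cbind(df, b, w)
  attr(out, "basis") <- basis
  out
}

#' Grand reference composition
#'
#' The compositional centre used as the reference point of substitution
#' analyses: by default the closed geometric mean, over persons, of each
#' person's geometric-mean composition (persons weighted equally); with
#' `weighting = "pooled"` the geometric mean over all nights. Scaled to the
#' mean time in bed.
#'
#' @param df Table per [sleep_table_columns()] (incomplete nights ignored).
#' @param weighting `"person"` (default) or `"pooled"`.
#' @param delta Zero-replacement duration in minutes.
#' @return List with `minutes` (named 4-vector summing to `tib`),
#'   `proportions`, and `tib` (mean time in bed, minutes).
#' @export
reference_composition <- function(df, weighting = c("person", "pooled"),
                                  delta = 0.5) {
  weighting <- match.arg(weighting)
  validate_sleep_table(df)
  comp <- as.matrix(df[, part_cols()])
  keep <- stats::complete.cases(comp) & !is.na(df$tib_min)
  if (!any(keep)) stop("no complete nights available")
  df <- df[keep, , drop = FALSE]
  comp <- comp[keep, , drop = FALSE]
  comp <- t(vapply(seq_len(nrow(comp)),
                   function(i) replace_zeros(comp[i, ], df$tib_min[i], delta),
                   numeric(ncol(comp))))
  if (weighting == "person") {
    person_means <- t(vapply(unique(df$id), function(pid) {
      gmean_comp(comp[df$id == pid, , drop = FALSE])
    }, numeric(ncol(comp))))
    prop <- gmean_comp(person_means)
  } else {
    prop <- gmean_comp(comp)
  }
  names(prop) <- SLEEP_PARTS
  tib <- mean(df$tib_min)
  list(minutes = prop * tib, proportions = prop, tib = tib)
}
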