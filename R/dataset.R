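# Packaged study data: the 48-polyester table, the literature-vs-in-house
# assay confusion matrix, and the pH-endpoint labelling rule of the
# high-throughput enzymatic biodegradation assay.

TABLE1_MD5 <- "0f1b00f64857c7b0ffd380ef110479e6"
CONFUSION_MD5 <- "47a6122306df5bb4e394f338c5f897d1"

#' Load the 48-polyester study dataset
#'
#' One row per polymer: the monomer pair, number-average and weight-average
#' molar masses (g/mol; `NA` where not determined), dispersity, the binary
#' biodegradability call of the enzymatic assay, and whether the polymer also
#' appears in the external literature dataset.
#'
#' @param path optional path to an alternative CSV (checksum verification is
#'   skipped for user-supplied files).
#' @return a tibble with columns `id`, `monomer1`, `monomer2`, `mn`, `mw`,
#'   `dispersity`, `label` (logical), `in_literature` (logical).
#' @export
load_table1 <- function(path = NULL) {
  packaged <- is.null(path)
  if (packaged) path <- system.file("extdata", "table1.csv", package = "polybiodeg")
  if (packaged && !identical(unname(tools::md5sum(path)), TABLE1_MD5)) {
    abort("packaged dataset fixture failed its integrity check",
          class = "polybiodeg_data_integrity_error")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = "n.d.")
  tbl <- as_tibble(raw) %>%
    mutate(
      id = as.integer(.data$id),
      monomer2 = ifelse(is.na(.data$monomer2) | .data$monomer2 == "", NA_character_,
                        .data$monomer2),
      mn = as.numeric(.data$mn),
      mw = as.numeric(.data$mw),
      dispersity = as.numeric(.data$dispersity),
      label = .data$biodegradable == "Yes",
      in_literature = .data$in_literature == 1
    ) %>%
    select(-"biodegradable")
  stopifnot(
    !anyDuplicated(tbl$id),
    setequal(tbl$id, seq_len(nrow(tbl))),
    all(tbl$mw >= tbl$mn, na.rm = TRUE)
  )
  tbl
}

#' Load the literature-vs-in-house assay confusion matrix
#'
#' @param path optional path to an alternative JSON file.
#' @return a 2x2 integer matrix; rows are the literature assay call, columns
#'   the in-house assay call, both ordered (biodegradable, non-biodegradable).
#' @export
load_assay_confusion <- function(path = NULL) {
  packaged <- is.null(path)
  if (packaged) path <- system.file("extdata", "assay_confusion.json", package = "polybiodeg")
  if (packaged && !identical(unname(tools::md5sum(path)), CONFUSION_MD5)) {
    abort("packaged confusion-matrix fixture failed its integrity check",
          class = "polybiodeg_data_integrity_error")
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(as.integer(t(j$counts)), nrow = 2, byrow = TRUE,
              dimnames = list(literature = j$row_labels, in_house = j$col_labels))
  stopifnot(all(m >= 0))
  m
}

#' Fraction of agreeing calls in a 2x2 assay confusion matrix
#'
#' @param table a 2x2 non-negative count matrix.
#' @return the diagonal sum divided by the total.
#' @export
assay_agreement <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2, ncol(table) == 2, all(table >= 0))
  total <- sum(table)
  if (total == 0) abort("confusion table has zero total count",
                        class = "polybiodeg_contract_error")
  sum(diag(table)) / total
}

#' Configuration of the pH-endpoint biodegradability call
#'
#' @param ph_cutoff pH below which a polymer is called biodegradable
#'   (default 5.4, indicative of diacid release).
#' @param t_end assay endpoint in hours (default 18.5; the long timeframe
#'   avoids bias towards fast-degrading polyesters).
#' @param sampling_interval measurement interval in minutes (default 30).
#' @return an `assay_config` object.
#' @export
assay_config <- function(ph_cutoff = 5.4, t_end = 18.5, sampling_interval = 30) {
  stopifnot(ph_cutoff > 0, ph_cutoff < 14, t_end > 0, sampling_interval > 0)
  structure(list(ph_cutoff = ph_cutoff, t_end = t_end,
                 sampling_interval = sampling_interval),
            class = "assay_config")
}

#' Apply the endpoint labelling rule to a pH trace
#'
#' The call is made on the measurement at (or nearest at-or-before) the assay
#' endpoint, not on any earlier crossing: a transient dip below the cutoff
#' followed by recovery is not called biodegradable.
#'
#' @param trace a data frame with columns `times` (minutes from enzyme
#'   addition, strictly increasing from 0) and `ph`.
#' @param cfg an [assay_config()].
#' @return `TRUE` iff the endpoint pH is below `cfg$ph_cutoff`.
#' @export
label_from_trace <- function(trace, cfg = assay_config()) {
  trace <- as_tibble(trace)
  stopifnot(all(c("times", "ph") %in% names(trace)), nrow(trace) >= 1,
            trace$times[1] == 0, !is.unsorted(trace$times, strictly = TRUE))
  t_end_min <- cfg$t_end * 60
  if (max(trace$times) < t_end_min) {
    abort(sprintf("trace ends at %g min but the assay endpoint is %g min",
                  max(trace$times), t_end_min),
          class = "polybiodeg_coverage_error")
  }
  at <- max(which(trace$times <= t_end_min))
  trace$ph[at] < cfg$ph_cutoff
}
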