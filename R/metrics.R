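#' Paired error metrics for measurement evaluation
#'
#' Automated measurements are scored against manual ground truth per
#' trait with three metrics over the n paired values: root mean square
#' error, mean absolute error, and mean relative error (each absolute
#' difference divided by the manual value before averaging). RMSE is in
#' cm, MAE in cm, MRE dimensionless; RMSE >= MAE always.
#'
#' @param estimated,measured equal-length numeric vectors of automated
#'   and manual values (cm). `measured` must be strictly positive for
#'   [mre()].
#' @return A non-negative scalar.
#' @name error_metrics
NULL

check_pairs <- function(estimated, measured, need_positive = FALSE) {
  if (length(estimated) == 0L || length(estimated) != length(measured))
    stop("estimated and measured must be non-empty and of equal length",
         call. = FALSE)
  if (!all(is.finite(estimated)) || !all(is.finite(measured)))
    stop("non-finite values in measurement pairs", call. = FALSE)
  if (need_positive && any(measured <= 0))
    stop("measured values must be > 0 for relative error", call. = FALSE)
}

#' @rdname error_metrics
#' @export
rmse <- function(estimated, measured) {
  check_pairs(estimated, measured)
  sqrt(mean((estimated - measured)^2))
}

#' @rdname error_metrics
#' @export
mae <- function(estimated, measured) {
  check_pairs(estimated, measured)
  mean(abs(estimated - measured))
}

#' @rdname error_metrics
#' @export
mre <- function(estimated, measured) {
  check_pairs(estimated, measured, need_positive = TRUE)
  mean(abs(estimated - measured) / measured)
}

TRAIT_CODES <- c("FL", "BL", "BH", "BT", "HL", "THH", "THW")
TRAIT_NAMES <- c(FL = "Full length", BL = "Body length", BH = "Body height",
                 BT = "Body thickness", HL = "Head length",
                 THH = "Tail handle height", THW = "Tail handle width")

#' Per-trait and average error report
#'
#' Computes MRE, MAE and RMSE for every shared trait column of two
#' measurement tables, plus an unweighted average of each metric across
#' traits. When both tables carry a `specimen_id` column the rows are
#' matched on it (an error lists any unmatched ids); otherwise rows are
#' paired by position.
#'
#' @param estimated,reference data frames with trait columns (any of
#'   `FL`, `BL`, `BH`, `BT`, `HL`, `THH`, `THW`, in cm) and optionally
#'   `specimen_id`.
#' @return Data frame of class `error_report` with columns `category`,
#'   `MRE`, `MAE`, `RMSE`; one row per trait plus an `Average` row.
#' @export
evaluate_errors <- function(estimated, reference) {
  if ("specimen_id" %in% names(estimated) && "specimen_id" %in% names(reference)) {
    miss_e <- setdiff(reference$specimen_id, estimated$specimen_id)
    miss_r <- setdiff(estimated$specimen_id, reference$specimen_id)
    if (length(miss_e) || length(miss_r))
      stop("unmatched specimen ids: ",
           paste(unique(c(miss_e, miss_r)), collapse = ", "), call. = FALSE)
    estimated <- estimated[match(reference$specimen_id, estimated$specimen_id), ]
  } else if (nrow(estimated) != nrow(reference)) {
    stop("tables differ in row count and carry no specimen_id to match on",
         call. = FALSE)
  }
  traits <- TRAIT_CODES[TRAIT_CODES %in% names(estimated) &
                        TRAIT_CODES %in% names(reference)]
  if (!length(traits))
    stop("no shared trait columns between the two tables", call. = FALSE)
  rows <- lapply(traits, function(tr) {
    data.frame(category = unname(TRAIT_NAMES[tr]),
               MRE = mre(estimated[[tr]], reference[[tr]]),
               MAE = mae(estimated[[tr]], reference[[tr]]),
               RMSE = rmse(estimated[[tr]], reference[[tr]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(category = "Average", MRE = mean(out$MRE),
                               MAE = mean(out$MAE), RMSE = mean(out$RMSE)))
  class(out) <- c("error_report", class(out))
  out
}

#' Write an error report as CSV and/or JSON
#'
#' @param report an [evaluate_errors()] result.
#' @param csv_path,json_path output paths; either may be `NULL` to skip.
#' @return Invisible list of written paths.
#' @export
write_error_report <- function(report, csv_path = NULL, json_path = NULL) {
  written <- list()
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE,
                     quote = FALSE)
    written$csv <- csv_path
  }
  if (!is.null(json_path)) {
    obj <- split(report[c("MRE", "MAE", "RMSE")], seq_len(nrow(report)))
    names(obj) <- report$category
    obj <- lapply(obj, as.list)
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written$json <- json_path
  }
  invisible(written)
}

#' Manual and automated measurements of 20 channel catfish
#'
#' The bundled reference dataset: seven traits for 20 channel catfish
#' (12-17 cm total length), measured both manually by an experienced
#' researcher and by the automated dual-view keypoint pipeline. Serves
#' as the regression anchor for the error metrics.
#'
#' @param which `"manual"`, `"auto"`, or `"both"` (default).
#' @return `"both"`: list with `manual` and `auto` data frames, each
#'   with `specimen_id` plus the seven trait columns (cm); otherwise the
#'   single requested data frame.
#' @export
catfish_measurements <- function(which = c("both", "manual", "auto")) {
  which <- match.arg(which)
  path <- system.file("extdata", "catfish20_measurements.csv",
                      package = "fishmetry", mustWork = TRUE)
  raw <- utils::read.csv(path, check.names = FALSE)
  pick <- function(prefix) {
    out <- raw[paste0(prefix, "_", TRAIT_CODES)]
    names(out) <- TRAIT_CODES
    cbind(specimen_id = as.character(raw$index), out)
  }
  switch(which,
         manual = pick("manual"),
         auto = pick("auto"),
         both = list(manual = pick("manual"), auto = pick("auto")))
}
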