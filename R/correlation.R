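# Descriptor-activity correlation (Pearson), with the join plumbing.

#' Pearson product-moment correlation
#'
#' Thin validated wrapper over [stats::cor()]: requires equal length >= 3,
#' finite values, and nonzero variance on both sides (a zero-variance input
#' is an error, never a silent 0).
#'
#' @param x,y numeric vectors.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite (drop or handle missing values first)")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Join a descriptor table with docking records
#'
#' Inner join on `compound_id`; rows with missing values in any correlated
#' column are dropped with a message (never imputed).
#'
#' @param descriptors table from [descriptor_table()].
#' @param docking data.frame with `compound_id`, `binding_energy`.
#' @param descriptors_cols descriptor columns to keep.
#' @return data.frame with descriptor columns plus `binding_energy`.
#' @export
build_property_table <- function(descriptors, docking,
                                 descriptors_cols = c("mu", "omega", "eta",
                                                      "softness", "gap")) {
  tab <- merge(descriptors[, c("compound_id", descriptors_cols)],
               docking[, c("compound_id", "binding_energy")],
               by = "compound_id")
  use <- c(descriptors_cols, "binding_energy")
  ok <- stats::complete.cases(tab[, use])
  if (any(!ok))
    message("dropping ", sum(!ok), " row(s) with missing values")
  tab <- tab[ok, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Descriptor-vs-activity correlation matrix
#'
#' One Pearson r per descriptor column against the binding energy, in a fixed
#' column order, with the sample size embedded. Set `negate_score = TRUE` to
#' correlate against `-binding_energy` (flips every sign) when scores are
#' reported as positive magnitudes.
#'
#' @param table data.frame from [build_property_table()] (or any table with
#'   the descriptor columns and `binding_energy`).
#' @param descriptors descriptor column names.
#' @param negate_score correlate against the negated binding energy.
#' @param p_values attach a two-sided t-based p-value column.
#' @return data.frame with columns `descriptor`, `r`, `n` (and `p` if
#'   requested).
#' @export
correlation_matrix <- function(table,
                               descriptors = c("mu", "omega", "eta",
                                               "softness", "gap"),
                               negate_score = FALSE, p_values = FALSE) {
  miss <- setdiff(c(descriptors, "binding_energy"), names(table))
  if (length(miss))
    stop("table lacks column(s): ", paste(miss, collapse = ", "))
  y <- table$binding_energy
  if (negate_score) y <- -y
  if (nrow(table) < 3L) stop("need at least 3 rows")
  out <- data.frame(descriptor = descriptors,
                    r = vapply(descriptors,
                               function(d) pearson_r(table[[d]], y), numeric(1)),
                    n = nrow(table), stringsAsFactors = FALSE)
  if (p_values)
    out$p <- vapply(descriptors, function(d)
      stats::cor.test(table[[d]], y)$p.value, numeric(1))
  rownames(out) <- NULL
  out
}
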