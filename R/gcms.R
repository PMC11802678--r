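#' Normalise GC-MS peak areas within samples
#'
#' Expresses each detected compound's peak area as a percentage of the total
#' peak area of all identified molecules in its sample.
#'
#' @param peaks data.frame with at least \code{sample_id} and \code{area}
#'   (arbitrary units, >= 0) columns.
#' @return the input with an added \code{pct} column; percentages sum to 100
#'   within each sample.
#' @export
normalise_peak_areas <- function(peaks) {
  if (!all(c("sample_id", "area") %in% names(peaks))) {
    stop("peak table needs sample_id and area columns")
  }
  if (any(peaks$area < 0, na.rm = TRUE)) stop("peak areas must be >= 0")
  totals <- tapply(peaks$area, peaks$sample_id, sum)
  if (any(totals <= 0)) {
    stop("zero total peak area for sample(s): ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  }
  peaks$pct <- 100 * peaks$area / as.numeric(totals[as.character(peaks$sample_id)])
  peaks
}

#' Parse an elemental formula
#'
#' @param formula character vector like \code{"C10H16"} or \code{"C7H6O2"}.
#' @return matrix with columns \code{C}, \code{H}, \code{O} (counts).
#' @keywords internal
parse_formula <- function(formula) {
  out <- matrix(0L, nrow = length(formula), ncol = 3,
                dimnames = list(NULL, c("C", "H", "O")))
  for (i in seq_along(formula)) {
    f <- gsub("[[:space:]_]", "", formula[i])
    if (is.na(f) || !grepl("^([A-Z][a-z]?[0-9]*)+$", f)) {
      stop("unparseable elemental formula: '", formula[i], "'")
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    for (tok in toks) {
      el <- gsub("[0-9]", "", tok)
      ct <- gsub("[^0-9]", "", tok)
      ct <- if (nzchar(ct)) as.integer(ct) else 1L
      if (el %in% colnames(out)) out[i, el] <- out[i, el] + ct
    }
  }
  out
}

#' Compound classes tracked in needle lipid extracts
#' @keywords internal
compound_classes <- c("monoterpene", "sesquiterpene",
                      "oxidation_C7_C8", "oxidation_C20plus", "other")

#' Classify a compound by elemental formula
#'
#' Formula-driven classification into the four terpenoid/oxidation-product
#' classes tracked in needle lipid extracts: exact C10H16 -> monoterpene,
#' exact C15H24 -> sesquiterpene, oxygen-containing compounds with 7-8
#' carbons -> \code{oxidation_C7_C8}, oxygen-containing with >= 20 carbons ->
#' \code{oxidation_C20plus}, everything else -> \code{other}. An override map
#' (named character vector, compound name -> class) handles edge compounds.
#'
#' @param formula character vector of elemental formulas.
#' @param compound optional compound names, consulted against
#'   \code{overrides}.
#' @param overrides named character vector mapping compound names to classes.
#' @return character vector of class labels.
#' @examples
#' classify_compound(c("C10H16", "C7H6O2", "C29H50O2"))
#' @export
classify_compound <- function(formula, compound = NULL, overrides = NULL) {
  cnt <- parse_formula(formula)
  cls <- rep("other", length(formula))
  mono <- cnt[, "C"] == 10 & cnt[, "H"] == 16 & cnt[, "O"] == 0
  sesq <- cnt[, "C"] == 15 & cnt[, "H"] == 24 & cnt[, "O"] == 0
  ox78 <- cnt[, "O"] >= 1 & cnt[, "C"] >= 7 & cnt[, "C"] <= 8
  ox20 <- cnt[, "O"] >= 1 & cnt[, "C"] >= 20
  cls[ox78] <- "oxidation_C7_C8"
  cls[ox20] <- "oxidation_C20plus"
  cls[mono] <- "monoterpene"
  cls[sesq] <- "sesquiterpene"
  if (!is.null(overrides) && !is.null(compound)) {
    hit <- compound %in% names(overrides)
    cls[hit] <- unname(overrides[compound[hit]])
    if (!all(cls %in% compound_classes)) stop("override maps to unknown class")
  }
  cls
}

#' Aggregate compound percentages into class composition profiles
#'
#' Sums normalised compound percentages within each class per sample. All
#' five classes (including \code{other}) are always present, so profiles sum
#' to 100 within each sample.
#'
#' @param peaks normalised peak table (see [normalise_peak_areas()]) with
#'   columns \code{sample_id}, \code{formula}, \code{pct} and optionally
#'   \code{compound}, \code{ozonation_category}, \code{species}, \code{zone}.
#' @param overrides passed to [classify_compound()].
#' @return data.frame with one row per sample x class: \code{sample_id},
#'   carried-over grouping columns, \code{class}, \code{pct}.
#' @export
aggregate_classes <- function(peaks, overrides = NULL) {
  if (!"pct" %in% names(peaks)) peaks <- normalise_peak_areas(peaks)
  if (!"formula" %in% names(peaks)) stop("peak table needs a formula column")
  peaks$class <- classify_compound(peaks$formula, peaks$compound, overrides)
  carry <- intersect(c("ozonation_category", "species", "zone"), names(peaks))
  out <- do.call(rbind, lapply(split(peaks, peaks$sample_id), function(g) {
    pct <- vapply(compound_classes,
                  function(cl) sum(g$pct[g$class == cl]), numeric(1))
    row <- data.frame(sample_id = g$sample_id[1], class = compound_classes,
                      pct = unname(pct))
    for (cc in carry) row[[cc]] <- g[[cc]][1]
    row
  }))
  rownames(out) <- NULL
  out
}

#' One-way fixed-effects ANOVA of class percentages
#'
#' Classical one-way ANOVA (equal-variance F test) comparing a class
#' percentage across ozonation categories, with group means and 0.95
#' t-based confidence intervals. Zero within-group variance with unequal
#' means is reported as \code{F = Inf}, \code{p = 0}.
#'
#' @param values numeric vector of class percentages.
#' @param groups factor (or coercible) of group labels, >= 2 levels.
#' @return list of class \code{oxs_anova}: \code{F}, \code{p}, \code{df}
#'   (between, within) and \code{means} (data.frame \code{group}, \code{n},
#'   \code{mean}, \code{lwr}, \code{upr}).
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  values <- as.numeric(values)
  if (length(values) != length(groups)) stop("values and groups differ in length")
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2) stop("need at least 2 groups")
  if (n <= k) stop("degenerate group sizes: need total n > number of groups")
  if (any(table(groups) < 1)) stop("empty group")
  gm <- tapply(values, groups, mean)
  ssw <- sum((values - gm[groups])^2)
  if (ssw == 0) {
    if (max(gm) - min(gm) > 0) {
      res <- list(F = Inf, p = 0, df = c(between = k - 1L, within = n - k))
    } else {
      res <- list(F = 0, p = 1, df = c(between = k - 1L, within = n - k))
    }
  } else {
    ow <- stats::oneway.test(values ~ groups, var.equal = TRUE)
    res <- list(F = unname(ow$statistic), p = unname(ow$p.value),
                df = c(between = unname(ow$parameter[1]),
                       within = unname(ow$parameter[2])))
  }
  means <- do.call(rbind, lapply(levels(groups), function(l) {
    v <- values[groups == l]
    se <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    half <- if (length(v) > 1) stats::qt(0.975, length(v) - 1) * se else NA_real_
    data.frame(group = l, n = length(v), mean = mean(v),
               lwr = mean(v) - half, upr = mean(v) + half)
  }))
  res$means <- means
  class(res) <- "oxs_anova"
  res
}

#' @export
print.oxs_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%g, %g) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Read a GC-MS peak table from CSV
#'
#' Expects columns \code{sample_id}, \code{species}, \code{zone},
#' \code{ozonation_category} (A = ambient, B = 3 h, C = 10 h),
#' \code{retention_index}, \code{compound}, \code{formula}, \code{area}.
#'
#' @param path path to the CSV file.
#' @return data.frame.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- c("sample_id", "ozonation_category", "compound", "formula", "area")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  df
}
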