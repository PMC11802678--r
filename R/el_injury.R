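#' Electrolyte-leakage injury index
#'
#' Converts one electrolyte-leakage (EL) conductivity assay into an injury
#' index \code{INX}, the percentage of total electrolytes already leaked
#' before cell membranes are destroyed in the autoclave. Conductivity of the
#' needle solution and of an ultrapure-water blank is measured before and
#' after autoclaving (121 degC, 20 min):
#' \deqn{INX = 100 \frac{c_{fresh} - c_{blank,fresh}}{c_{auto} - c_{blank,auto}}}
#'
#' All arguments are vectorised and recycled to a common length. Results are
#' clipped to \code{[0, 100]}: small negative values (down to
#' \code{-clip_negative}, measurement noise around the blank) are set to 0
#' with a warning, larger negatives are an error; values above 100 are
#' likewise clipped with a warning.
#'
#' @param c_blank_fresh conductivity (uS/cm) of the water blank before
#'   autoclaving.
#' @param c_fresh conductivity (uS/cm) of the needle solution before
#'   autoclaving.
#' @param c_blank_auto conductivity (uS/cm) of the water blank after
#'   autoclaving.
#' @param c_auto conductivity (uS/cm) of the needle solution after
#'   autoclaving.
#' @param sample_id optional sample labels used in error messages.
#' @param clip_negative tolerance (percentage points) below zero within which
#'   a negative index is treated as noise and clipped to 0. Default 0.5.
#' @return numeric vector of injury indices in percent, in \code{[0, 100]}.
#' @examples
#' injury_index(2, 12, 2, 52) # 20
#' @export
injury_index <- function(c_blank_fresh, c_fresh, c_blank_auto, c_auto,
                         sample_id = NULL, clip_negative = 0.5) {
  n <- max(length(c_blank_fresh), length(c_fresh),
           length(c_blank_auto), length(c_auto))
  c_blank_fresh <- rep_len(as.numeric(c_blank_fresh), n)
  c_fresh <- rep_len(as.numeric(c_fresh), n)
  c_blank_auto <- rep_len(as.numeric(c_blank_auto), n)
  c_auto <- rep_len(as.numeric(c_auto), n)
  if (is.null(sample_id)) sample_id <- as.character(seq_len(n))
  sample_id <- rep_len(as.character(sample_id), n)

  vals <- cbind(c_blank_fresh, c_fresh, c_blank_auto, c_auto)
  if (anyNA(vals)) {
    stop("missing conductivity value(s) for sample(s): ",
         paste(sample_id[apply(is.na(vals), 1, any)], collapse = ", "))
  }
  if (any(vals < 0)) {
    stop("negative raw conductivity for sample(s): ",
         paste(sample_id[apply(vals < 0, 1, any)], collapse = ", "))
  }
  denom <- c_auto - c_blank_auto
  if (any(denom <= 0)) {
    stop("invalid measurement (post-autoclave conductivity does not exceed ",
         "its blank) for sample(s): ",
         paste(sample_id[denom <= 0], collapse = ", "))
  }
  inx <- 100 * (c_fresh - c_blank_fresh) / denom
  bad_neg <- inx < -clip_negative
  if (any(bad_neg)) {
    stop("injury index below -", clip_negative,
         " (pre-autoclave solution far below blank) for sample(s): ",
         paste(sample_id[bad_neg], collapse = ", "))
  }
  if (any(inx < 0)) {
    warning("clipping ", sum(inx < 0), " slightly negative injury index(es) to 0")
    inx[inx < 0] <- 0
  }
  if (any(inx > 100)) {
    warning("clipping ", sum(inx > 100), " injury index(es) above 100 to 100")
    inx[inx > 100] <- 100
  }
  inx
}

#' Injury indices from a replicated conductivity table
#'
#' Applies [injury_index()] to every row of a conductivity table and averages
#' replicates within each species x zone x series cell. The index is computed
#' per replicate first and then averaged, and the replicate standard deviation
#' is reported alongside.
#'
#' @param measurements data.frame with columns \code{sample_id},
#'   \code{species}, \code{zone}, \code{series_index} (integer 1..6),
#'   \code{c_blank_fresh}, \code{c_fresh}, \code{c_blank_auto}, \code{c_auto}.
#' @param ... passed on to [injury_index()].
#' @return data.frame with one row per species x zone x series_index and
#'   columns \code{inx} (mean, percent), \code{inx_sd} and \code{n_rep}.
#' @export
injury_indices <- function(measurements, ...) {
  req <- c("sample_id", "species", "zone", "series_index",
           "c_blank_fresh", "c_fresh", "c_blank_auto", "c_auto")
  miss <- setdiff(req, names(measurements))
  if (length(miss)) {
    stop("conductivity table is missing column(s): ", paste(miss, collapse = ", "))
  }
  m <- measurements
  m$.inx <- injury_index(m$c_blank_fresh, m$c_fresh, m$c_blank_auto,
                         m$c_auto, sample_id = m$sample_id, ...)
  key <- interaction(m$species, m$zone, m$series_index, drop = TRUE, sep = "\r")
  agg <- do.call(rbind, lapply(split(m, key), function(g) {
    data.frame(species = g$species[1], zone = g$zone[1],
               series_index = g$series_index[1],
               inx = mean(g$.inx),
               inx_sd = if (nrow(g) > 1) stats::sd(g$.inx) else NA_real_,
               n_rep = nrow(g))
  }))
  agg <- agg[order(agg$zone, agg$species, agg$series_index), ]
  rownames(agg) <- NULL
  agg
}

#' Read a conductivity measurement table from CSV
#'
#' Expects a header row with columns \code{sample_id}, \code{species},
#' \code{zone}, \code{series_index}, \code{c_blank_fresh}, \code{c_fresh},
#' \code{c_blank_auto}, \code{c_auto} (UTF-8, decimal point).
#'
#' @param path path to the CSV file.
#' @return data.frame of conductivity measurements.
#' @export
read_conductivity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- c("sample_id", "species", "zone", "series_index",
           "c_blank_fresh", "c_fresh", "c_blank_auto", "c_auto")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  df$series_index <- as.integer(df$series_index)
  df
}
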