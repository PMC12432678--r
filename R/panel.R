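# Serum x bead MFI panels. Long format is canonical: one row per
# (serum, bead allele) with its MFI. Positivity uses a strict cutoff
# (MFI > cutoff, default 1000); missing MFIs are carried as NA and
# propagate as MISSING calls.

#' Build a serum panel
#'
#' @param df data.frame with columns \code{serum_id}, \code{allele},
#'   \code{mfi} (non-negative or NA).
#' @param cutoff Positivity cutoff; a bead is positive when its MFI is
#'   strictly greater. Default 1000.
#' @return A \code{serum_panel}.
#' @export
serum_panel <- function(df, cutoff = 1000) {
  stopifnot(is.data.frame(df),
            all(c("serum_id", "allele", "mfi") %in% names(df)))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a single positive number", call. = FALSE)
  d <- data.frame(serum_id = as.character(df$serum_id),
                  allele = allele_key(df$allele),
                  mfi = as.numeric(df$mfi),
                  stringsAsFactors = FALSE)
  if (any(d$mfi < 0, na.rm = TRUE))
    stop("negative MFI values are not allowed", call. = FALSE)
  if (anyDuplicated(d[, c("serum_id", "allele")]))
    stop("duplicate (serum_id, allele) measurements", call. = FALSE)
  structure(list(data = d, cutoff = cutoff), class = "serum_panel")
}

#' Read a serum panel from CSV
#'
#' @param path CSV file. Long format (\code{serum_id,allele,mfi}) by
#'   default; with \code{wide = TRUE}, a serum x allele matrix whose first
#'   column is \code{serum_id} and remaining column names are bead alleles.
#' @param wide Logical; wide-matrix input.
#' @param cutoff Positivity cutoff.
#' @return A \code{serum_panel}.
#' @export
read_panel <- function(path, wide = FALSE, cutoff = 1000) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (wide) {
    if (names(df)[1] != "serum_id")
      stop("wide panel must have 'serum_id' as its first column", call. = FALSE)
    long <- do.call(rbind, lapply(names(df)[-1], function(a)
      data.frame(serum_id = df$serum_id, allele = a, mfi = df[[a]],
                 stringsAsFactors = FALSE)))
    df <- long
  }
  serum_panel(df, cutoff = cutoff)
}

#' @export
print.serum_panel <- function(x, ...) {
  cat(sprintf("<serum_panel> %d sera x %d beads, %d measurements, cutoff %g\n",
              length(unique(x$data$serum_id)), length(unique(x$data$allele)),
              nrow(x$data), x$cutoff))
  invisible(x)
}

#' Score bead positivity for one serum
#'
#' POS when MFI strictly exceeds the panel cutoff, NEG otherwise, MISSING
#' when the MFI is absent.
#'
#' @param panel A \code{serum_panel}.
#' @param serum_id Serum to score (must be present).
#' @return data.frame \code{allele}, \code{mfi}, \code{score}.
#' @export
score_positivity <- function(panel, serum_id) {
  stopifnot(inherits(panel, "serum_panel"))
  d <- panel$data[panel$data$serum_id == serum_id, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("serum not present in panel: ", serum_id, call. = FALSE)
  score <- ifelse(is.na(d$mfi), "MISSING",
                  ifelse(d$mfi > panel$cutoff, "POS", "NEG"))
  data.frame(allele = d$allele, mfi = d$mfi, score = score,
             stringsAsFactors = FALSE)
}

#' Pairwise regression between two beads across sera
#'
#' Ordinary least squares of bead-Y MFI on bead-X MFI over the sera that
#' have both beads measured and show positive reactivity on at least one of
#' them (MFI > \code{inclusion_cutoff}). With fewer than two included sera
#' the result is flagged degenerate and carries no fit values.
#'
#' @param panel A \code{serum_panel}.
#' @param allele_x,allele_y Bead alleles.
#' @param inclusion_cutoff Serum-inclusion threshold (default 1000).
#' @return A \code{sab_regression}: list with \code{allele_x},
#'   \code{allele_y}, \code{n_sera}, \code{slope}, \code{intercept},
#'   \code{r_squared}, \code{included} (serum ids), \code{degenerate}.
#' @export
pairwise_regression <- function(panel, allele_x, allele_y,
                                inclusion_cutoff = 1000) {
  stopifnot(inherits(panel, "serum_panel"))
  m <- pair_mfi(panel, allele_x, allele_y)
  inc <- m[!is.na(m$x) & !is.na(m$y) &
             (m$x > inclusion_cutoff | m$y > inclusion_cutoff), , drop = FALSE]
  res <- list(allele_x = allele_key(allele_x), allele_y = allele_key(allele_y),
              n_sera = nrow(inc), slope = NA_real_, intercept = NA_real_,
              r_squared = NA_real_, included = inc$serum_id,
              degenerate = TRUE)
  if (nrow(inc) >= 2L && stats::var(inc$x) > 0) {
    fit <- stats::lm(y ~ x, data = inc)
    res$slope <- unname(stats::coef(fit)[2])
    res$intercept <- unname(stats::coef(fit)[1])
    res$r_squared <- stats::cor(inc$x, inc$y)^2
    res$degenerate <- FALSE
  }
  class(res) <- "sab_regression"
  res
}

#' @export
print.sab_regression <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("<sab_regression> %s ~ %s: degenerate (n = %d)\n",
                x$allele_y, x$allele_x, x$n_sera))
  else
    cat(sprintf("<sab_regression> %s ~ %s: n = %d, slope = %.3f, R^2 = %.3f\n",
                x$allele_y, x$allele_x, x$n_sera, x$slope, x$r_squared))
  invisible(x)
}

pair_mfi <- function(panel, allele_x, allele_y) {
  kx <- allele_key(allele_x); ky <- allele_key(allele_y)
  d <- panel$data
  dx <- d[d$allele == kx, c("serum_id", "mfi")]
  dy <- d[d$allele == ky, c("serum_id", "mfi")]
  if (nrow(dx) == 0L || nrow(dy) == 0L)
    stop("bead(s) not present in panel: ",
         paste(c(kx, ky)[c(nrow(dx) == 0L, nrow(dy) == 0L)], collapse = ", "),
         call. = FALSE)
  m <- merge(dx, dy, by = "serum_id", suffixes = c(".x", ".y"))
  data.frame(serum_id = m$serum_id, x = m$mfi.x, y = m$mfi.y,
             stringsAsFactors = FALSE)
}

#' Sera with strongly discordant reactivity between two beads
#'
#' The symmetric-outlier screen: sera reacting strongly with one bead
#' (MFI > \code{high_cutoff}) and negatively with the other
#' (MFI < \code{low_cutoff}). Both inequalities are strict.
#'
#' @param panel A \code{serum_panel}.
#' @param allele_x,allele_y Bead alleles.
#' @param high_cutoff Strong-reactivity threshold (typical presets: 8000
#'   for the database-wide screen, 5000 for targeted follow-up).
#' @param low_cutoff Negativity threshold (default 1000).
#' @return list with \code{xy} (high on X, negative on Y) and \code{yx}
#'   (the symmetric case); disjoint serum-id vectors, sorted.
#' @export
find_discordant_sera <- function(panel, allele_x, allele_y, high_cutoff,
                                 low_cutoff = 1000) {
  if (high_cutoff <= low_cutoff)
    stop("high_cutoff must exceed low_cutoff", call. = FALSE)
  m <- pair_mfi(panel, allele_x, allele_y)
  m <- m[!is.na(m$x) & !is.na(m$y), , drop = FALSE]
  list(xy = sort(m$serum_id[m$x > high_cutoff & m$y < low_cutoff]),
       yx = sort(m$serum_id[m$y > high_cutoff & m$x < low_cutoff]))
}

#' Screen a list of bead pairs
#'
#' Runs \code{pairwise_regression} and \code{find_discordant_sera} for each
#' pair and returns one summary row per pair.
#'
#' @param panel A \code{serum_panel}.
#' @param pairs data.frame with columns \code{allele_x}, \code{allele_y}.
#' @param high_cutoff,low_cutoff Discordance thresholds.
#' @param inclusion_cutoff Regression inclusion threshold.
#' @return data.frame with fit statistics and discordant-serum lists
#'   (comma-joined) per pair.
#' @export
screen_pairs <- function(panel, pairs, high_cutoff = 8000, low_cutoff = 1000,
                         inclusion_cutoff = 1000) {
  stopifnot(all(c("allele_x", "allele_y") %in% names(pairs)))
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    x <- pairs$allele_x[i]; y <- pairs$allele_y[i]
    fit <- pairwise_regression(panel, x, y, inclusion_cutoff)
    disc <- find_discordant_sera(panel, x, y, high_cutoff, low_cutoff)
    data.frame(allele_x = fit$allele_x, allele_y = fit$allele_y,
               n_sera = fit$n_sera, slope = fit$slope,
               intercept = fit$intercept, r_squared = fit$r_squared,
               n_discordant_xy = length(disc$xy),
               n_discordant_yx = length(disc$yx),
               discordant_xy = paste(disc$xy, collapse = ","),
               discordant_yx = paste(disc$yx, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Score a flow crossmatch
#'
#' Median channel shift (MCS) cutoffs are inclusive: a T-cell crossmatch is
#' positive at MCS >= 92, a B-cell crossmatch at MCS >= 116.
#'
#' @param compartment \code{"T"} or \code{"B"} (vectorised).
#' @param mcs Numeric MCS value(s).
#' @param t_cutoff,b_cutoff Positivity cutoffs (defaults 92 and 116).
#' @return Character vector of \code{"POS"}/\code{"NEG"}.
#' @export
score_fxm <- function(compartment, mcs, t_cutoff = 92, b_cutoff = 116) {
  compartment <- toupper(as.character(compartment))
  if (!all(compartment %in% c("T", "B")))
    stop("compartment must be 'T' or 'B'", call. = FALSE)
  cut <- ifelse(compartment == "T", t_cutoff, b_cutoff)
  ifelse(mcs >= cut, "POS", "NEG")
}
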