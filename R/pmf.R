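# Potentials of mean force and free-energy barriers.
#
# The reversible-work relation W(r) = -kBT ln g(r) turns a pair RDF into a
# free-energy profile along the pair distance; a barrier is the difference
# between the first local maximum and the preceding first local minimum of
# W(r), reported in kBT and optionally converted to kcal/mol with an
# explicit factor.

#' Potential of mean force from an RDF
#'
#' `W(r) = -ln g(r)` in kBT units on bins where `g > 0`; bins with `g = 0`
#' are undefined (`NA`), not zero and not capped — a vanishing g carries no
#' free-energy information at finite sampling.
#'
#' @param rdf an `rdf_curve`
#' @param temperature simulation temperature in K, carried as metadata
#'   (W is expressed in kBT units, so the numerical profile does not depend
#'   on it)
#' @return an object of class `pmf_curve`: `r_centers`, `W` (kBT, `NA`
#'   where undefined), `defined` (logical), `temperature`
#' @export
rdf_to_pmf <- function(rdf, temperature = 310.15) {
  stopifnot(inherits(rdf, "rdf_curve"))
  W <- ifelse(rdf$g > 0, -log(rdf$g), NA_real_)
  structure(
    list(r_centers = rdf$r_centers, W = W, defined = rdf$g > 0,
         temperature = as.numeric(temperature)),
    class = "pmf_curve"
  )
}

#' @export
print.pmf_curve <- function(x, ...) {
  cat("<pmf_curve> ", length(x$W), " bins, ", sum(x$defined),
      " defined, min W = ",
      if (any(x$defined)) round(min(x$W, na.rm = TRUE), 3) else NA,
      " kBT\n", sep = "")
  invisible(x)
}

# first index of each strict local extremum on a numeric vector; plateaus
# resolve to their first index (ties broken toward smaller r)
local_extrema <- function(w) {
  n <- length(w)
  if (n < 3L) return(list(minima = integer(0), maxima = integer(0)))
  minima <- integer(0); maxima <- integer(0)
  for (i in 2:(n - 1L)) {
    # nearest differing neighbours (handles flat plateaus)
    l <- i - 1L
    while (l > 1L && w[l] == w[i]) l <- l - 1L
    r <- i + 1L
    while (r < n && w[r] == w[i]) r <- r + 1L
    if (w[l] == w[i] || w[r] == w[i]) next
    if (w[i] == w[i - 1L]) next  # plateau interior: keep only first index
    if (w[i] < w[l] && w[i] < w[r]) minima <- c(minima, i)
    if (w[i] > w[l] && w[i] > w[r]) maxima <- c(maxima, i)
  }
  list(minima = minima, maxima = maxima)
}

#' Extract the first free-energy barrier from a PMF
#'
#' Finds the first local minimum of `W(r)` (smallest r) inside the search
#' window and the first local maximum at larger r, and reports the barrier
#' `delta_W = W(max) - W(min)` in kBT plus its kcal/mol conversion.
#' Candidate pairs whose rise is below the prominence threshold are treated
#' as sampling noise and skipped. If the window contains no
#' minimum-then-maximum pattern the result is a distinct "no barrier"
#' outcome (`found = FALSE`), not a zero barrier.
#'
#' @param pmf a `pmf_curve`
#' @param window numeric length-2 search window in Angstrom (default
#'   1-6 Angstrom, spanning the hydrogen-bond first shell and the second
#'   shells around 4-5 Angstrom)
#' @param prominence minimum rise W(max) - W(min) in kBT for a pair of
#'   extrema to count as a barrier (default 0.05)
#' @param smooth_window optional odd integer; if given, g-level noise is
#'   damped by a centred moving average of W over this many bins before
#'   extremum search (barrier heights are still read off the smoothed
#'   curve)
#' @param kcal_per_kbt conversion factor passed to [kbt_to_kcal()]
#' @return an object of class `barrier_result` with `found`, `r_min`,
#'   `W_min`, `r_max`, `W_max`, `delta_W` (kBT), `delta_W_kcal`
#' @export
extract_barrier <- function(pmf, window = c(1, 6), prominence = 0.05,
                            smooth_window = NULL, kcal_per_kbt = 0.596) {
  stopifnot(inherits(pmf, "pmf_curve"))
  no_barrier <- structure(
    list(found = FALSE, r_min = NA_real_, W_min = NA_real_,
         r_max = NA_real_, W_max = NA_real_, delta_W = NA_real_,
         delta_W_kcal = NA_real_),
    class = "barrier_result"
  )

  in_win <- pmf$r_centers >= window[1] & pmf$r_centers <= window[2] & pmf$defined
  if (!any(in_win)) return(no_barrier)
  # extrema are determined on the r-ordered sequence of defined bins:
  # undefined bins (g = 0 at finite sampling) are skipped rather than
  # treated as infinite walls, so sparsely sampled regions between the
  # first shell and the background do not mask the barrier
  idx <- which(in_win)
  if (length(idx) < 3L) return(no_barrier)

  w <- pmf$W[idx]
  if (!is.null(smooth_window)) {
    sw <- as.integer(smooth_window)
    if (sw %% 2L != 1L || sw < 1L) stop("smooth_window must be a positive odd integer")
    if (sw > 1L) {
      kern <- rep(1 / sw, sw)
      w <- as.numeric(stats::filter(w, kern, sides = 2))
      keep <- !is.na(w)
      idx <- idx[keep]; w <- w[keep]
      if (length(idx) < 3L) return(no_barrier)
    }
  }

  ext <- local_extrema(w)
  if (length(ext$minima) == 0L || length(ext$maxima) == 0L) return(no_barrier)

  for (m in ext$minima) {
    after <- ext$maxima[ext$maxima > m]
    for (M in after) {
      dW <- w[M] - w[m]
      if (dW >= prominence) {
        return(structure(
          list(found = TRUE,
               r_min = pmf$r_centers[idx[m]], W_min = w[m],
               r_max = pmf$r_centers[idx[M]], W_max = w[M],
               delta_W = dW, delta_W_kcal = kbt_to_kcal(dW, kcal_per_kbt)),
          class = "barrier_result"
        ))
      }
    }
  }
  no_barrier
}

#' @export
print.barrier_result <- function(x, ...) {
  if (!x$found) {
    cat("<barrier_result> no barrier found\n")
  } else {
    cat(sprintf(
      "<barrier_result> min W = %.3f kBT at r = %.3f A; max W = %.3f kBT at r = %.3f A; dW = %.3f kBT (%.1f kcal/mol)\n",
      x$W_min, x$r_min, x$W_max, x$r_max, x$delta_W, x$delta_W_kcal))
  }
  invisible(x)
}

#' Convert a free energy from kBT to kcal/mol
#'
#' Multiplies by an explicit conversion factor (default 0.596 kcal/mol per
#' kBT, the convention used for barrier reporting in this package). The
#' factor is never silently recomputed from a temperature; pass your own if
#' you want a different convention. Rounding is left to the presentation
#' layer.
#'
#' @param delta_W free energy in kBT
#' @param factor kcal/mol per kBT, > 0
#' @return free energy in kcal/mol
#' @export
#' @examples
#' round(kbt_to_kcal(5.2), 1)  # 3.1
#' round(kbt_to_kcal(1.2), 1)  # 0.7
kbt_to_kcal <- function(delta_W, factor = 0.596) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop("factor must be a single positive number")
  }
  delta_W * factor
}
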