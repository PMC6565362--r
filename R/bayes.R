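# The probabilistic layer: von Mises likelihoods for two cues, a
# zero-centered von Mises prior on the stimulus discrepancy, the integrated
# posterior and the cue-disparity distribution, recovery of the single-cue
# posterior from the pair, and the Gaussian-approximation information-loss
# fraction.

# Documented sentinel for "infinite" concentration; resultant_length treats
# anything at or above it as 1 through effective_kappa's clamp.
.KAPPA_INF <- 1e12

#' Pair of cues with likelihood and prior concentrations
#'
#' Bundles the quantities entering two-cue circular inference: cue
#' directions \code{x1}, \code{x2} (degrees), likelihood concentrations
#' \code{kappa1}, \code{kappa2} (reliability of each cue), and the prior
#' concentration \code{kappa_s} coupling the two stimulus features (the
#' prior says the two features tend to have similar values; \code{kappa_s}
#' sets how strongly). Infinite concentrations may be passed as \code{Inf}
#' and are stored as the sentinel 1e12.
#'
#' @param x1,x2 cue directions in degrees, wrapped to (-180, 180].
#' @param kappa1,kappa2 likelihood concentrations, \code{>= 0}.
#' @param kappa_s prior concentration, \code{>= 0}.
#' @return an object of class \code{"cue_pair"}.
#' @examples
#' cue_pair(0, 20, 50, 50, 50)
#' @export
cue_pair <- function(x1, x2, kappa1, kappa2, kappa_s) {
  ks <- c(kappa1 = kappa1, kappa2 = kappa2, kappa_s = kappa_s)
  ks[is.infinite(ks)] <- .KAPPA_INF
  if (any(ks < 0) || any(!is.finite(ks)))
    stop("concentrations must be >= 0 (Inf allowed, stored as 1e12 sentinel)")
  structure(list(x1 = wrap_angle(x1), x2 = wrap_angle(x2),
                 kappa1 = unname(ks[1]), kappa2 = unname(ks[2]),
                 kappa_s = unname(ks[3])),
            class = "cue_pair")
}

#' @export
print.cue_pair <- function(x, ...) {
  cat(sprintf("cue pair: x1 = %g deg (kappa1 = %g), x2 = %g deg (kappa2 = %g), prior kappa_s = %g\n",
              x$x1, x$kappa1, x$x2, x$kappa2, x$kappa_s))
  invisible(x)
}

# memoized root-finding cache for effective_kappa
.ek_cache <- new.env(parent = emptyenv())

#' Effective concentration of the indirect cue
#'
#' The posterior of stimulus 1 given only the indirect cue x2 is
#' approximately von Mises with concentration \code{kappa_2s} defined by
#' equating mean resultant lengths:
#' \code{A(kappa_2s) = A(kappa2) * A(kappa_s)}. The prior thus discounts the
#' indirect cue; in the large-concentration (Gaussian) limit
#' \code{1/kappa_2s ~ 1/kappa2 + 1/kappa_s}. Solved numerically by
#' bracketed root-finding (tolerance 1e-10) with memoization; concentrations
#' at or above the 1e12 sentinel are treated as infinite (A = 1).
#'
#' @param kappa2 concentration of the indirect cue's likelihood.
#' @param kappa_s prior concentration.
#' @return \code{kappa_2s <= min(kappa2, kappa_s)}.
#' @examples
#' effective_kappa(50, 50)           # about 25.26
#' effective_kappa(50, Inf)          # 50: infinitely tight prior
#' effective_kappa(50, 0)            # 0: flat prior carries no information
#' @export
effective_kappa <- function(kappa2, kappa_s) {
  stopifnot(kappa2 >= 0, kappa_s >= 0)
  A <- function(k) if (k >= .KAPPA_INF) 1 else resultant_length(k)
  if (is.infinite(kappa2)) kappa2 <- .KAPPA_INF
  if (is.infinite(kappa_s)) kappa_s <- .KAPPA_INF
  if (kappa2 >= .KAPPA_INF) return(kappa_s)
  if (kappa_s >= .KAPPA_INF) return(kappa2)
  if (kappa2 == 0 || kappa_s == 0) return(0)
  key <- paste(format(kappa2, digits = 17), format(kappa_s, digits = 17))
  hit <- .ek_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- A(kappa2) * A(kappa_s)
  out <- inv_resultant(r)
  .ek_cache[[key]] <- out
  out
}

#' Integrated posterior of stimulus 1 given both cues
#'
#' Optimal integration multiplies the single-cue posteriors, i.e. sums the
#' corresponding vectors: the direct-cue vector \code{(x1, kappa1)} plus the
#' indirect-cue vector \code{(x2, kappa_2s)} with \code{kappa_2s} from
#' \code{\link{effective_kappa}}.
#'
#' @param c a \code{\link{cue_pair}}.
#' @return a \code{\link{von_mises}} posterior. Exact cancellation returns
#'   kappa 0 with the undefined-mu flag.
#' @examples
#' posterior_integrated(cue_pair(0, 20, 50, 50, 50))
#' @export
posterior_integrated <- function(c) {
  stopifnot(inherits(c, "cue_pair"))
  k2s <- effective_kappa(c$kappa2, c$kappa_s)
  vm_product(von_mises(c$x1, c$kappa1), von_mises(c$x2, k2s))
}

#' Cue-disparity distribution of stimulus 1 given both cues
#'
#' The disparity information is the ratio of the two single-cue posteriors,
#' i.e. the vector difference: direct-cue vector minus indirect-cue vector.
#' Its concentration grows with cue conflict while the integrated
#' concentration shrinks, so comparing the two vector lengths assesses
#' whether the cues should be integrated or segregated.
#'
#' @param c a \code{\link{cue_pair}}.
#' @return a \code{\link{von_mises}} distribution; identical single-cue
#'   posteriors give kappa 0 with the undefined-mu flag (no disparity
#'   signal).
#' @examples
#' posterior_disparity(cue_pair(0, 20, 50, 50, 50))
#' @export
posterior_disparity <- function(c) {
  stopifnot(inherits(c, "cue_pair"))
  k2s <- effective_kappa(c$kappa2, c$kappa_s)
  vm_ratio(von_mises(c$x1, c$kappa1), von_mises(c$x2, k2s))
}

#' Recover the single-cue posterior from integration and disparity
#'
#' Averaging the log of the integrated posterior and the log of the
#' disparity distribution cancels the indirect-cue terms and returns the
#' posterior given the direct cue alone:
#' \code{ln p(s1|x1) = [ln p(s1|x1,x2) + ln pd(s1|x1,x2)] / 2}, i.e. the
#' half-sum of the two vectors, which equals \code{(x1, kappa1)} exactly.
#'
#' @param integrated,disparity \code{von_mises} outputs of
#'   \code{\link{posterior_integrated}} and \code{\link{posterior_disparity}}
#'   on the same cue pair.
#' @return a \code{\link{von_mises}} distribution.
#' @examples
#' cp <- cue_pair(-30, 40, 30, 60, 50)
#' recover_single_cue(posterior_integrated(cp), posterior_disparity(cp))
#' @export
recover_single_cue <- function(integrated, disparity) {
  vec_to_vm((vm_to_vec(integrated) + vm_to_vec(disparity)) / 2)
}

#' Fraction of direct-cue Fisher information lost by integration
#'
#' Under the large-concentration Gaussian approximation, the Fisher
#' information about cue 1 retained in the integrated posterior falls short
#' of the likelihood's by the fraction
#' \code{(1/kappa1) / (1/kappa1 + 1/kappa2 + 1/kappa_s)}. The loss grows
#' with the prior concentration \code{kappa_s} (more integration, more
#' single-cue information sacrificed) and reaches 1 in the full-integration
#' limit \code{kappa2, kappa_s -> Inf}.
#'
#' @param kappa1,kappa2 likelihood concentrations, \code{> 0} (Inf allowed).
#' @param kappa_s prior concentration, \code{>= 0} (Inf allowed; 0 means no
#'   integration hence no loss).
#' @return fraction in \code{[0, 1]}.
#' @examples
#' info_loss_fraction(50, 50, 50)   # 1/3
#' info_loss_fraction(50, 50, 0)    # 0
#' info_loss_fraction(50, Inf, Inf) # 1
#' @export
info_loss_fraction <- function(kappa1, kappa2, kappa_s) {
  if (kappa1 <= 0 || kappa2 <= 0 || kappa_s < 0)
    stop("kappa1, kappa2 must be > 0 and kappa_s >= 0")
  if (kappa_s == 0) return(0)
  i1 <- 1 / kappa1; i2 <- 1 / kappa2; is <- 1 / kappa_s
  i1 / (i1 + i2 + is)
}
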