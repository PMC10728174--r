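#' Parameterised DSB mutation spectrum
#'
#' Bundles the generative parameters of the synthetic sequencing model. The
#' defaults emulate the mutation burden observed around restriction-enzyme
#' induced DSBs at deep amplicon coverage: a substitution peak at the cut
#' decaying exponentially over ~20 bp, small (1 bp), mid (2-5 bp) and large
#' (>5 bp) break-adjacent deletions at per-read probabilities matching
#' published per-DSB totals of 0.22%, 0.094% and 0.17%, distant 1-bp slippage
#' deletions at homopolymer runs, microhomology-mediated (MMEJ) deletions
#' (junction homology 2-7 bp, up to 70 bp deleted; 0.068% per DSB), rare
#' insertions (0.05% per DSB), rare translocation chimeras (~0.01%), and a
#' uniform per-base sequencing-error floor.
#'
#' All `*_rate` parameters are per-read (or per-read-pair for
#' `transloc_rate`) event probabilities; `sub_rate_peak` is a per-read,
#' per-position probability at the cut and `sub_floor` the distant
#' per-position floor. `sub_signature` weights the six pyrimidine-collapsed
#' substitution classes and must sum to 1.
#'
#' @param sub_rate_peak Per-read substitution probability per position at
#'   the cut midpoint.
#' @param sub_decay_bp Exponential decay length (bp) of the substitution
#'   peak.
#' @param sub_floor Distant per-position substitution floor (also the only
#'   induced-substitution term at UNCUT loci).
#' @param sub_signature Named weights over `C>A, C>G, C>T, T>A, T>C, T>G`.
#' @param del_small_rate,del_mid_rate,del_large_rate Per-read probabilities
#'   of break-adjacent 1 bp, 2-5 bp and >5 bp deletions.
#' @param distant_slip_rate Per-read probability of a distant 1-bp deletion
#'   at a homopolymer run (length >= 3).
#' @param mmej_rate Per-read probability of a large cut-spanning deletion
#'   with 2-7 bp junction microhomology.
#' @param ins_rate Per-read insertion probability (1-3 bp, near the cut).
#' @param transloc_rate Per-read-pair probability of a chimeric (trans)
#'   pair.
#' @param transloc_weights Optional weight matrix over ordered locus pairs
#'   (rownames = fwd locus, colnames = rev locus); `NULL` = uniform over
#'   ordered pairs of distinct cut loci.
#' @param seq_error_rate Uniform per-base substitution error.
#' @param seed Default RNG seed used when the simulators are called without
#'   one.
#' @return A `mutation_spectrum` list.
#' @export
mutation_spectrum <- function(sub_rate_peak = 2.5e-4,
                              sub_decay_bp = 20,
                              sub_floor = 2e-7,
                              sub_signature = c("C>A" = 0.18, "C>G" = 0.22,
                                                "C>T" = 0.35, "T>A" = 0.08,
                                                "T>C" = 0.10, "T>G" = 0.07),
                              del_small_rate = 0.0022,
                              del_mid_rate = 0.00094,
                              del_large_rate = 0.0017,
                              distant_slip_rate = 0.001,
                              mmej_rate = 0.00068,
                              ins_rate = 5e-4,
                              transloc_rate = 1e-4,
                              transloc_weights = NULL,
                              seq_error_rate = 0.001,
                              seed = NA_integer_) {
  sp <- list(sub_rate_peak = sub_rate_peak, sub_decay_bp = sub_decay_bp,
             sub_floor = sub_floor, sub_signature = sub_signature,
             del_small_rate = del_small_rate, del_mid_rate = del_mid_rate,
             del_large_rate = del_large_rate,
             distant_slip_rate = distant_slip_rate, mmej_rate = mmej_rate,
             ins_rate = ins_rate, transloc_rate = transloc_rate,
             transloc_weights = transloc_weights,
             seq_error_rate = seq_error_rate, seed = seed)
  class(sp) <- "mutation_spectrum"
  validate_spectrum(sp)
  sp
}

SIGNATURE_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

validate_spectrum <- function(sp) {
  rates <- c(sp$sub_rate_peak, sp$sub_floor, sp$del_small_rate,
             sp$del_mid_rate, sp$del_large_rate, sp$distant_slip_rate,
             sp$mmej_rate, sp$ins_rate, sp$transloc_rate, sp$seq_error_rate)
  if (any(rates < 0 | rates > 1))
    stop("mutation_spectrum: all rates must lie in [0, 1]")
  if (sp$sub_decay_bp <= 0) stop("mutation_spectrum: sub_decay_bp must be > 0")
  sig <- sp$sub_signature
  if (!identical(sort(names(sig)), sort(SIGNATURE_CLASSES)))
    stop("mutation_spectrum: sub_signature must be named over ",
         paste(SIGNATURE_CLASSES, collapse = ", "))
  if (any(sig < 0) || abs(sum(sig) - 1) > 1e-8)
    stop("mutation_spectrum: sub_signature weights must be >= 0 and sum to 1")
  invisible(sp)
}

#' A spectrum with every mutagenic process switched off
#'
#' Convenience for undamaged (-DSB) samples and null controls: all event
#' rates zero; sequencing error kept unless `seq_error_rate = 0`.
#'
#' @inheritParams mutation_spectrum
#' @return A `mutation_spectrum`.
#' @export
null_spectrum <- function(seq_error_rate = 0.001, seed = NA_integer_) {
  mutation_spectrum(sub_rate_peak = 0, sub_floor = 0, del_small_rate = 0,
                    del_mid_rate = 0, del_large_rate = 0,
                    distant_slip_rate = 0, mmej_rate = 0, ins_rate = 0,
                    transloc_rate = 0, seq_error_rate = seq_error_rate,
                    seed = seed)
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("mutation_spectrum\n")
  cat(sprintf("  substitutions: peak %.3g / position at cut, decay %g bp, floor %.3g\n",
              x$sub_rate_peak, x$sub_decay_bp, x$sub_floor))
  cat(sprintf("  deletions (per read): small %.3g, mid %.3g, large %.3g, slippage %.3g, MMEJ %.3g\n",
              x$del_small_rate, x$del_mid_rate, x$del_large_rate,
              x$distant_slip_rate, x$mmej_rate))
  cat(sprintf("  insertions %.3g, translocations %.3g / pair, sequencing error %.3g / base\n",
              x$ins_rate, x$transloc_rate, x$seq_error_rate))
  invisible(x)
}
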