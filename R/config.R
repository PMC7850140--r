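#' Caller configuration
#'
#' Collects every numeric threshold used by the SV-calling pipeline in one
#' place. Defaults follow the published method: candidate breakpoints need a
#' clip longer than 5 bp; the per-site support threshold is 10% of the local
#' sequencing coverage; discordant pairs exceed
#' \code{min(mean + sd, mean + 300)} of the insert size; read extension works
#' in 1 kb bins with a minimum overlap of 30 bp and a 3 bp boundary
#' tolerance; local assembly extracts a 1.2 kb window and runs k-mers 41, 61
#' and 81; the complex-alignment rescue requires mapping quality >= 50 and a
#' high-quality-base ratio >= 0.8; translocation split evidence requires
#' mapping quality > 20 on both sides.
#'
#' @param min_clip Minimum clip length (strict, bp) for a read to count as
#'   clipped.
#' @param support_frac Fraction of coverage defining the support threshold X.
#' @param min_support_floor Lower bound on X; a lone read never nominates a
#'   candidate.
#' @param discordant_pad Cap (bp) added to the insert-size mean in the
#'   discordant-pair threshold.
#' @param bin_width Pairing distance (bp) for read extension.
#' @param min_overlap_n Minimum head-to-tail overlap (strict, bp) for a join.
#' @param boundary_shift Bases discounted at each end of the compared
#'   overlap.
#' @param assembly_window Width (bp) of the local-assembly read window.
#' @param kmers Integer vector of de Bruijn k-mer sizes.
#' @param complex_mapq,complex_hq_ratio Thresholds for the
#'   complex-read-alignment decision node.
#' @param tra_mapq Strict lower bound on mapping quality for both sides of a
#'   translocation split read.
#' @param min_sv Minimum event size (bp) separating SVs from indels.
#' @param min_mapq Mapping-quality floor for clipped reads entering
#'   extension, candidate collection and assembly.
#' @param chunk_width Genome chunk width (bp) for the scanning pipeline.
#' @param chunk_margin Extra margin (bp) scanned past each chunk edge so
#'   extension bins and candidate windows never straddle a hard boundary.
#' @param spliced_window Half-width (bp) of the reference window used by the
#'   builtin spliced aligner.
#' @param match_window Breakpoint window (bp) used for evidence exclusion and
#'   truth matching.
#' @param cluster_pos_tol,cluster_size_tol Evidence-merging tolerances:
#'   positions within \code{cluster_pos_tol} bp and sizes within
#'   \code{cluster_size_tol} (fraction) merge.
#' @param backend Spliced-alignment backend, \code{"builtin"} or
#'   \code{"minimap2"}.
#' @param emit_indels Emit sub-\code{min_sv} indels resolved at the CIGAR
#'   decision node into the output (default drops them).
#'
#' @return A list of class \code{"caller_config"}.
#' @export
caller_config <- function(min_clip = 5L, support_frac = 0.10,
                          min_support_floor = 2L, discordant_pad = 300L,
                          bin_width = 1000L, min_overlap_n = 30L,
                          boundary_shift = 3L, assembly_window = 1200L,
                          kmers = c(41L, 61L, 81L), complex_mapq = 50L,
                          complex_hq_ratio = 0.8, tra_mapq = 20L,
                          min_sv = 50L, min_mapq = 20L,
                          chunk_width = 1e6, chunk_margin = 10000L,
                          spliced_window = 50000L, match_window = 200L,
                          cluster_pos_tol = 10L, cluster_size_tol = 0.2,
                          backend = c("builtin", "minimap2"),
                          emit_indels = FALSE) {
  backend <- match.arg(backend)
  cfg <- list(
    min_clip = as.integer(min_clip), support_frac = support_frac,
    min_support_floor = as.integer(min_support_floor),
    discordant_pad = as.integer(discordant_pad),
    bin_width = as.integer(bin_width),
    min_overlap_n = as.integer(min_overlap_n),
    boundary_shift = as.integer(boundary_shift),
    assembly_window = as.integer(assembly_window),
    kmers = as.integer(kmers), complex_mapq = as.integer(complex_mapq),
    complex_hq_ratio = complex_hq_ratio, tra_mapq = as.integer(tra_mapq),
    min_sv = as.integer(min_sv), min_mapq = as.integer(min_mapq),
    chunk_width = chunk_width, chunk_margin = as.integer(chunk_margin),
    spliced_window = as.integer(spliced_window),
    match_window = as.integer(match_window),
    cluster_pos_tol = as.integer(cluster_pos_tol),
    cluster_size_tol = cluster_size_tol,
    backend = backend, emit_indels = isTRUE(emit_indels)
  )
  check_that(cfg$support_frac > 0 && cfg$support_frac <= 1,
             "support_frac must be in (0, 1]")
  check_that(all(unlist(cfg[c("min_clip", "bin_width", "min_overlap_n",
                              "assembly_window", "min_sv")]) > 0),
             "thresholds must be positive")
  structure(cfg, class = "caller_config")
}

#' @export
print.caller_config <- function(x, ...) {
  cat("<caller_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(x[[nm]], collapse = ",")))
  }
  invisible(x)
}

#' Support threshold from sequencing coverage
#'
#' The per-site read-support threshold X is 10% of the sequencing coverage
#' (rounded up), with a floor of two reads so that a single read can never
#' nominate a candidate on its own.
#'
#' @param coverage Sequencing coverage (x).
#' @param support_frac Fraction of coverage (default 0.10).
#' @param floor Minimum value of X.
#' @return Integer threshold X.
#' @examples
#' support_threshold(30)   # 3
#' support_threshold(100)  # 10
#' @export
support_threshold <- function(coverage, support_frac = 0.10, floor = 2L) {
  check_that(coverage > 0, "coverage must be positive")
  max(as.integer(floor), as.integer(ceiling(support_frac * coverage)))
}
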