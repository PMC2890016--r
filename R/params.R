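#' Parameters for the four-taxon synthetic transcriptome generator
#'
#' Defaults emulate the study conditions of a hybrid Sanger/454 charophyte
#' EST survey: two charophyte-like focal taxa with distinct GC targets
#' (about 49% and 41%), a land-plant-like and a chlorophyte-like reference
#' genome, roughly 10% contaminant reads and about 20% of transcripts with
#' no coding region. Gene families evolve down the fixed species topology
#' `((ref_plant,(charoA,charoB)),ref_chlorophyte)` under a codon-level
#' substitution model with a 3:1 synonymous:nonsynonymous weight.
#'
#' @param n_families Number of gene families.
#' @param species_list Four unique species identifiers, in the order
#'   ref_plant, charoA, charoB, ref_chlorophyte.
#' @param presence_profile Data frame with columns `subset`
#'   (`+`-joined species names) and `prob`, summing to 1: the probability
#'   that a family is present in exactly that species subset.
#' @param divergence Named per-branch substitution rates (subs/site) for
#'   branches `streptophyte`, `ref_plant`, `charophyte`, `charoA`,
#'   `charoB`, `ref_chlorophyte` of the fixed topology.
#' @param paralog_rate Probability that a present species carries an extra
#'   duplicated copy.
#' @param utr_len Named mean lengths (nt) of the 5' and 3' UTRs
#'   (`utr5`, `utr3`).
#' @param cds_len Mean CDS length in codons.
#' @param gc_target Named per-taxon GC fraction targets.
#' @param contam_fraction Expected contaminant fraction of reads.
#' @param noncoding_fraction Fraction of transcripts with no CDS.
#' @param seed Integer seed; all generator stages derive child seeds from it.
#' @return A validated `generator_params` list.
#' @export
generator_params <- function(
    n_families = 200,
    species_list = c("ref_plant", "charoA", "charoB", "ref_chlorophyte"),
    presence_profile = NULL,
    divergence = c(streptophyte = 0.05, ref_plant = 0.15, charophyte = 0.05,
                   charoA = 0.08, charoB = 0.08, ref_chlorophyte = 0.35),
    paralog_rate = 0.05,
    utr_len = c(utr5 = 80, utr3 = 150),
    cds_len = 250,
    gc_target = c(ref_plant = 0.44, charoA = 0.49, charoB = 0.41,
                  ref_chlorophyte = 0.52),
    contam_fraction = 0.10,
    noncoding_fraction = 0.20,
    seed = 1L) {
  stopifnot(length(species_list) == 4, !anyDuplicated(species_list))
  if (n_families < 1) stop("n_families must be >= 1")
  if (cds_len < 1) stop("zero-length CDS requested")
  stopifnot(all(divergence >= 0),
            all(names(c(streptophyte = 0)) %in% names(divergence)))
  need <- c("streptophyte", "ref_plant", "charophyte", "charoA", "charoB",
            "ref_chlorophyte")
  if (!all(need %in% names(divergence))) {
    stop("divergence must name branches: ", paste(need, collapse = ", "))
  }
  probs <- c(paralog_rate, contam_fraction, noncoding_fraction, gc_target)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!setequal(names(gc_target), species_list)) {
    names(gc_target) <- species_list
  }
  if (is.null(presence_profile)) {
    s <- species_list
    presence_profile <- tibble(
      subset = c(paste(s, collapse = "+"),
                 paste(s[1:3], collapse = "+"),
                 paste(s[2:3], collapse = "+"),
                 paste(s[2:4], collapse = "+"),
                 paste(s[c(1, 2)], collapse = "+"),
                 paste(s[c(1, 3)], collapse = "+"),
                 s[2], s[3], s[1], s[4]),
      prob = c(0.45, 0.15, 0.12, 0.06, 0.05, 0.05, 0.04, 0.04, 0.02, 0.02))
  }
  stopifnot(abs(sum(presence_profile$prob) - 1) < 1e-8,
            all(presence_profile$prob >= 0))
  structure(list(
    n_families = as.integer(n_families), species_list = species_list,
    presence_profile = as_tibble(presence_profile),
    divergence = divergence, paralog_rate = paralog_rate,
    utr_len = utr_len, cds_len = cds_len, gc_target = gc_target,
    contam_fraction = contam_fraction,
    noncoding_fraction = noncoding_fraction,
    seed = as.integer(seed)), class = "generator_params")
}

#' Read-technology error model
#'
#' Defaults follow the read-length statistics of the emulated survey:
#' long, low-error, 5'-anchored Sanger reads (mean 915 nt) and shorter 454
#' reads (mean 378 nt) that start anywhere on the transcript, carry a
#' library adapter and make +/-1 errors in homopolymer runs.
#'
#' @param technology `"sanger"` or `"flx454"`.
#' @param mean_len,len_sd Read length distribution (nt).
#' @param substitution_rate Per-base substitution error rate.
#' @param homopolymer_indel_rate Per-run (length >= 3) probability of a
#'   +/-1 length error (454 only).
#' @param five_prime_anchored Do reads start at transcript position 0?
#' @param adapter_seq Adapter string prepended to each raw read.
#' @return A validated `read_model` list.
#' @export
read_model <- function(technology = c("sanger", "flx454"),
                       mean_len = NULL, len_sd = NULL,
                       substitution_rate = NULL,
                       homopolymer_indel_rate = NULL,
                       five_prime_anchored = NULL,
                       adapter_seq = NULL) {
  technology <- match.arg(technology)
  def <- if (technology == "sanger") {
    list(mean_len = 915, len_sd = 150, substitution_rate = 0.002,
         homopolymer_indel_rate = 0, five_prime_anchored = TRUE,
         adapter_seq = "")
  } else {
    list(mean_len = 378, len_sd = 60, substitution_rate = 0.005,
         homopolymer_indel_rate = 0.01, five_prime_anchored = FALSE,
         adapter_seq = "GCCTCCCTCGCGCCATCAG")
  }
  m <- list(technology = technology,
            mean_len = mean_len %||% def$mean_len,
            len_sd = len_sd %||% def$len_sd,
            substitution_rate = substitution_rate %||% def$substitution_rate,
            homopolymer_indel_rate =
              homopolymer_indel_rate %||% def$homopolymer_indel_rate,
            five_prime_anchored =
              five_prime_anchored %||% def$five_prime_anchored,
            adapter_seq = adapter_seq %||% def$adapter_seq)
  stopifnot(m$mean_len > 0, m$len_sd >= 0,
            m$substitution_rate >= 0, m$substitution_rate <= 1,
            m$homopolymer_indel_rate >= 0, m$homopolymer_indel_rate <= 1)
  structure(m, class = "read_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read cleaning parameters
#'
#' @param adapters Character vector of adapter sequences to strip from
#'   read ends.
#' @param max_adapter_mismatch Maximum Hamming mismatches in an
#'   end-anchored adapter match.
#' @param quality_window Sliding-window length (nt) for quality trimming.
#' @param quality_floor Minimum window mean phred score.
#' @param min_len Reads shorter than this after trimming are discarded.
#' @param dust_threshold,dust_window DUST-style low-complexity score cutoff
#'   and window (nt).
#' @return A validated `trim_params` list.
#' @export
trim_params <- function(adapters = character(0), max_adapter_mismatch = 2,
                        quality_window = 20, quality_floor = 15,
                        min_len = 60, dust_threshold = 2, dust_window = 64) {
  stopifnot(min_len >= 1, max_adapter_mismatch >= 0, quality_window >= 1,
            quality_floor >= 0, dust_threshold >= 0, dust_window >= 3)
  structure(list(adapters = toupper(adapters),
                 max_adapter_mismatch = max_adapter_mismatch,
                 quality_window = quality_window,
                 quality_floor = quality_floor, min_len = min_len,
                 dust_threshold = dust_threshold, dust_window = dust_window),
            class = "trim_params")
}

#' Overlap-clustering parameters
#'
#' The acceptance rule is the classic one for EST assembly: a candidate
#' merge needs at least `min_overlap` aligned columns at `min_identity`
#' or better, identity being computed over the overlap region only.
#'
#' @param min_overlap Minimum overlap length (nt; default 100).
#' @param min_identity Minimum identity fraction over the overlap
#'   (default 0.95).
#' @param seed_k k-mer length used to propose candidate overlaps.
#' @param band Alignment band half-width around the seeded diagonal.
#' @return A validated `overlap_params` list.
#' @export
overlap_params <- function(min_overlap = 100, min_identity = 0.95,
                           seed_k = 12, band = 20) {
  stopifnot(min_identity > 0, min_identity <= 1, seed_k >= 4,
            min_overlap >= seed_k, band >= 1)
  structure(list(min_overlap = min_overlap, min_identity = min_identity,
                 seed_k = as.integer(seed_k), band = as.integer(band)),
            class = "overlap_params")
}

#' Protein/translated homology-search parameters
#'
#' Scores are converted to bit scores and E-values with fixed
#' Karlin-Altschul constants: `bit = (lambda*S - ln kappa)/ln 2` and
#' `E = kappa * m * n * exp(-lambda*S)` where m is the query length and n
#' the summed subject length.
#'
#' @param matrix_name Substitution matrix (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive).
#' @param seed_k Exact word length (amino acids) for seeding.
#' @param two_hit_window Max distance between two seed hits on a diagonal
#'   for the diagonal to be extended.
#' @param band Band half-width for the gapped extension.
#' @param lambda,kappa Karlin-Altschul constants.
#' @param evalue_cutoff Report hits with `E <= evalue_cutoff`.
#' @return A validated `aligner_params` list.
#' @export
aligner_params <- function(matrix_name = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, seed_k = 4, two_hit_window = 40,
                           band = 32, lambda = 0.267, kappa = 0.041,
                           evalue_cutoff = 10) {
  stopifnot(gap_open > 0, gap_extend > 0, seed_k >= 2, lambda > 0,
            kappa > 0, band >= 1, two_hit_window >= 1)
  structure(list(matrix_name = matrix_name, gap_open = gap_open,
                 gap_extend = gap_extend, seed_k = as.integer(seed_k),
                 two_hit_window = two_hit_window, band = as.integer(band),
                 lambda = lambda, kappa = kappa,
                 evalue_cutoff = evalue_cutoff),
            class = "aligner_params")
}
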