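#' Parameters for fragment-based average nucleotide identity
#'
#' The conventional fragment-ANI (ANIb-style) settings: the query genome is
#' cut into consecutive 1020-bp fragments, each is aligned to its best
#' location in the subject, and fragments are retained when the alignment
#' has at least 30% identity over at least 70% of the fragment.
#'
#' @param fragment_length fragment size in bp.
#' @param min_fragment_identity minimum fractional identity to keep a
#'   fragment.
#' @param min_fragment_coverage minimum aligned fraction of the fragment.
#' @param seed_kmer k-mer length used to seed the best-location search.
#' @param band half-width of the banded alignment around the seeded
#'   diagonal.
#' @param full_dp_limit when a fragment has no k-mer seed, a full-width
#'   alignment is attempted only if the subject totals at most this many
#'   bases.
#' @return An `ani_params` list.
#' @export
ani_params <- function(fragment_length = 1020L, min_fragment_identity = 0.30,
                       min_fragment_coverage = 0.70, seed_kmer = 15L,
                       band = 32L, full_dp_limit = 20000L) {
  stopifnot(fragment_length > 0,
            min_fragment_identity >= 0, min_fragment_identity <= 1,
            min_fragment_coverage >= 0, min_fragment_coverage <= 1,
            seed_kmer >= 4, seed_kmer <= 31, band >= 1)
  list(fragment_length = as.integer(fragment_length),
       min_fragment_identity = min_fragment_identity,
       min_fragment_coverage = min_fragment_coverage,
       seed_kmer = as.integer(seed_kmer),
       band = as.integer(band),
       full_dp_limit = as.integer(full_dp_limit))
}

seqs_of <- function(g) {
  if (inherits(g, "genome_record")) g$sequences
  else if (is.character(g)) g
  else stop("expected a genome_record or character vector of contigs")
}

#' Compute one-directional average nucleotide identity
#'
#' The query is cut into consecutive fixed-length fragments (trailing
#' partial fragments discarded); each fragment is aligned to its best
#' subject location (shared-k-mer seeding, banded extension); ANI is the
#' mean identity of the fragments passing the identity and coverage
#' filters, in percent. Identity is computed over unambiguous (A/C/G/T)
#' aligned columns only. Deterministic.
#'
#' @param query,subject [genome_record()]s or named character vectors of
#'   contig sequences.
#' @param params an [ani_params()] list.
#' @return List with `query`, `subject`, `ani` (percent; `NA` and
#'   `defined = FALSE` when no fragment passes), `n_fragments_used`,
#'   `n_fragments_total`.
#' @export
compute_ani <- function(query, subject, params = ani_params()) {
  qs <- seqs_of(query)
  ss <- seqs_of(subject)
  if (sum(nchar(qs)) == 0 || sum(nchar(ss)) == 0)
    stop("empty genome")
  fr <- cpp_ani_fragments(unname(qs), unname(ss),
                          params$fragment_length, params$seed_kmer,
                          params$band, 1.0, -1.0, -2.0,
                          params$full_dp_limit)
  used <- !is.na(fr$identity) &
    fr$identity >= params$min_fragment_identity &
    fr$coverage >= params$min_fragment_coverage
  ani <- if (any(used)) 100 * mean(fr$identity[used]) else NA_real_
  list(query = if (inherits(query, "genome_record")) query$strain_id else NA,
       subject = if (inherits(subject, "genome_record")) subject$strain_id else NA,
       ani = ani,
       defined = any(used),
       n_fragments_used = sum(used),
       n_fragments_total = nrow(fr))
}

#' Pairwise ANI matrix and species delineation
#'
#' Computes ANI in both directions for every genome pair, symmetrizes as the
#' mean of the two directions, and delineates species as the connected
#' components of the graph whose edges join pairs with ANI at or above the
#' cutoff (conventionally 95%).
#'
#' @param genomes named list of [genome_record()]s or of named contig
#'   vectors.
#' @param params an [ani_params()] list.
#' @param cutoff species-boundary ANI percentage.
#' @return List with `matrix` (symmetric ANI percent, `NA` on undefined
#'   pairs), `species` (named integer cluster membership), and
#'   `undefined_pairs` (data frame of pairs excluded from the graph).
#' @export
ani_matrix_and_species <- function(genomes, params = ani_params(),
                                   cutoff = 95) {
  stopifnot(is.list(genomes), length(genomes) >= 2, !is.null(names(genomes)))
  ids <- names(genomes)
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  undef <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      f <- compute_ani(genomes[[i]], genomes[[j]], params)
      r <- compute_ani(genomes[[j]], genomes[[i]], params)
      vals <- c(f$ani, r$ani)
      if (all(is.na(vals))) {
        undef[[length(undef) + 1L]] <- data.frame(g1 = ids[i], g2 = ids[j])
      } else {
        m[i, j] <- m[j, i] <- mean(vals, na.rm = TRUE)
      }
    }
  }
  adj <- !is.na(m) & m >= cutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  species <- igraph::components(g)$membership
  names(species) <- ids
  list(matrix = m, species = species,
       undefined_pairs = if (length(undef)) do.call(rbind, undef) else NULL)
}
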