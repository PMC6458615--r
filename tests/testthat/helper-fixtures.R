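# Shared fixtures and independent oracles for the test suite.

# Small two-lineage clade reused across modules (memoized per test file).
tiny_clade <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 42, ...) {
    key <- paste0("s", seed, "_", paste(deparse(list(...)), collapse = ""))
    if (is.null(cache[[key]])) {
      cfg <- clade_config(
        n_genomes = 6,
        lineage_assignment = rep(c("P", "L"), each = 3),
        n_core = 30, n_accessory = 20,
        accessory_presence_prob = 0.5,
        singleton_rate = 2,
        gene_length_range = c(300, 600),
        tree_branch_lengths = list(stem = 0.03, tip = 0.0025),
        seed = seed, ...)
      cache[[key]] <- simulate_clade(cfg)
    }
    cache[[key]]
  }
})

truth_matrix <- function(ds) {
  presence_absence_matrix(ds$truth$gene_map[, c("family_id", "strain")],
                          genomes = names(ds$genomes))
}

# Independent oracle: exhaustive global alignment score by recursion over
# all alignments (exponential; tiny inputs only).
oracle_align_score <- function(a, b, match, mismatch, gap) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- rec(i - 1, j - 1) +
        if (substring(a, i, i) == substring(b, j, j)) match else mismatch
      best <- max(best, s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# Independent oracle: plain R Needleman-Wunsch (score only), for inputs too
# large for the exhaustive recursion.
oracle_nw_score <- function(a, b, match, mismatch, gap) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  prev <- gap * (0:n)
  for (i in seq_len(m)) {
    cur <- numeric(n + 1)
    cur[1] <- gap * i
    for (j in seq_len(n)) {
      cur[j + 1] <- max(prev[j] + if (av[i] == bv[j]) match else mismatch,
                        prev[j + 1] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev[n + 1]
}

# Independent NG86 oracle for one codon pair: explicit recursion over
# substitution orderings, using Biostrings' genetic code directly.
oracle_codon_diffs <- function(c1, c2) {
  code <- Biostrings::getGeneticCode("11")
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(d) == 0) return(c(sd = 0, nd = 0))
  paths <- list()
  walk <- function(cur, remaining, sd, nd, stopped) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1L]] <<- c(sd = sd, nd = nd, stopped = stopped)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      substring(nxt, pos, pos) <- substring(c2, pos, pos)
      syn <- code[[nxt]] == code[[cur]]
      walk(nxt, setdiff(remaining, pos),
           sd + as.integer(syn), nd + as.integer(!syn),
           stopped || (code[[nxt]] == "*" && nxt != c2))
    }
  }
  walk(c1, d, 0, 0, FALSE)
  pm <- do.call(rbind, paths)
  ok <- pm[, "stopped"] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(pm))
  c(sd = mean(pm[ok, "sd"]), nd = mean(pm[ok, "nd"]))
}

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  sort(as.vector(outer(outer(b, b, paste0), b, paste0)))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random stop-free CDS
random_test_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  cods <- all_codons()
  cods <- cods[!cods %in% stops]
  paste(sample(cods, n_codons, replace = TRUE), collapse = "")
}
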