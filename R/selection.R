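# Nei-Gojobori (1986) pairwise dN/dS with equal-weight averaging over
# minimal mutational pathways. Conventions: mutations creating a stop codon
# count as nonsynonymous in site counting; pathways passing through a stop
# codon are excluded from difference counting (all pathways are used as a
# fallback if every ordering crosses a stop).

ng86_env <- new.env(parent = emptyenv())

codon_table <- function() {
  if (!is.null(ng86_env$aa)) return(ng86_env)
  code <- Biostrings::getGeneticCode("11")
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  aa <- code[codons]
  # synonymous site fraction per codon position: fraction of the 3 possible
  # single-base changes that preserve the amino acid (changes to stops are
  # nonsynonymous); stop codons themselves carry NA sites
  syn_sites <- matrix(NA_real_, length(codons), 3,
                      dimnames = list(codons, NULL))
  for (c1 in codons) {
    if (aa[c1] == "*") next
    for (pos in 1:3) {
      syn <- 0
      for (b in setdiff(bases, substring(c1, pos, pos))) {
        c2 <- c1
        substring(c2, pos, pos) <- b
        if (aa[c2] == aa[c1]) syn <- syn + 1
      }
      syn_sites[c1, pos] <- syn / 3
    }
  }
  ng86_env$aa <- aa
  ng86_env$codons <- codons
  ng86_env$syn_sites <- syn_sites
  ng86_env
}

# permutations of 1..k
perms <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  out <- NULL
  for (i in seq_len(k)) {
    sub <- perms(k - 1)
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

# Sd/Nd for one codon pair, averaged over admissible minimal pathways.
codon_pair_diffs <- function(c1, c2) {
  tb <- codon_table()
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diff_pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  ords <- perms(k)
  path_sd <- path_nd <- numeric(0)
  all_sd <- all_nd <- numeric(0)
  for (r in seq_len(nrow(ords))) {
    cur <- c1
    sd_ <- nd_ <- 0
    through_stop <- FALSE
    for (step in ords[r, ]) {
      pos <- diff_pos[step]
      nxt <- cur
      substring(nxt, pos, pos) <- substring(c2, pos, pos)
      if (tb$aa[nxt] == "*" && nxt != c2) through_stop <- TRUE
      if (tb$aa[nxt] == tb$aa[cur]) sd_ <- sd_ + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    all_sd <- c(all_sd, sd_); all_nd <- c(all_nd, nd_)
    if (!through_stop) { path_sd <- c(path_sd, sd_); path_nd <- c(path_nd, nd_) }
  }
  if (length(path_sd) == 0) { path_sd <- all_sd; path_nd <- all_nd }
  c(sd = mean(path_sd), nd = mean(path_nd))
}

split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

#' Pairwise dN/dS by the Nei-Gojobori method
#'
#' Counts synonymous (S) and nonsynonymous (N) sites by averaging the
#' synonymous fraction of each codon position over both sequences, counts
#' synonymous and nonsynonymous differences (Sd, Nd) by equal-weight
#' averaging over all minimal mutational pathways between differing codons
#' (pathways through stop codons excluded), Jukes-Cantor-corrects the
#' proportions (`d = -(3/4) ln(1 - 4p/3)`), and reports `omega = dN/dS`
#' with the selection classification: purifying (`omega < 1`), neutral,
#' positive (`omega > 1`), or undefined (`dS = 0` or saturated distances).
#'
#' @param cds1,cds2 equal-length, in-frame, gap-free coding sequences
#'   without internal stop codons.
#' @return List with `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`,
#'   `classification`.
#' @export
ng86_pairwise <- function(cds1, cds2) {
  if (nchar(cds1) != nchar(cds2)) stop("sequences must have equal length")
  if (nchar(cds1) %% 3 != 0) stop("sequence length must be a multiple of 3")
  if (grepl("-", cds1, fixed = TRUE) || grepl("-", cds2, fixed = TRUE))
    stop("sequences must be gap-free")
  tb <- codon_table()
  co1 <- split_codons(cds1)
  co2 <- split_codons(cds2)
  if (any(tb$aa[co1] == "*") || any(tb$aa[co2] == "*"))
    stop("internal stop codon in input")
  s1 <- sum(tb$syn_sites[co1, ])
  s2 <- sum(tb$syn_sites[co2, ])
  S <- (s1 + s2) / 2
  N <- 3 * length(co1) - S
  diffs <- vapply(seq_along(co1), function(i)
    codon_pair_diffs(co1[i], co2[i]), c(sd = 0, nd = 0))
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_) # saturated: correction undefined
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS)
  dN <- jc(pN)
  saturated <- (!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)
  omega <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
  classification <- if (saturated) "saturated"
    else if (is.na(omega)) "undefined"
    else if (omega < 1) "purifying"
    else if (omega > 1) "positive"
    else "neutral"
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = dS, dN = dN, omega = omega, classification = classification)
}

#' dN/dS table for a set of in-frame CDS pairs
#'
#' @param pairs data frame (or list of 2-vectors) with columns `id`, `cds1`,
#'   `cds2`.
#' @return Data frame with one row per pair: the NG86 quantities and
#'   classification.
#' @export
ng86_table <- function(pairs) {
  stopifnot(all(c("id", "cds1", "cds2") %in% names(pairs)))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- ng86_pairwise(pairs$cds1[i], pairs$cds2[i])
    data.frame(id = pairs$id[i], S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
               dS = r$dS, dN = r$dN, omega = r$omega,
               classification = r$classification, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
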