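#' Read a FASTA file into a named character vector
#'
#' Order-preserving, whitespace-tolerant, and case-normalizing: sequence
#' lines are uppercased so downstream identity and GC computations see a
#' single alphabet. Record names are the header text up to the first
#' whitespace.
#'
#' @param path file path or character vector of raw lines.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- sub("\r$", "", lines)
  ids <- character(0)
  chunks <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) {
      cur <- strsplit(trimws(substring(ln, 2)), "\\s+")[[1]][1]
      if (is.na(cur) || !nzchar(cur)) stop("empty FASTA header at line ", i)
      ids <- c(ids, cur)
      chunks[[cur]] <- character(0)
    } else {
      if (is.null(cur))
        stop("FASTA parse error: sequence before first header at line ", i)
      chunks[[cur]] <- c(chunks[[cur]], gsub("\\s", "", ln))
    }
  }
  out <- vapply(chunks, function(x) toupper(paste(x, collapse = "")), "")
  out[ids]
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line-wrap width in characters.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    if (nchar(s) == 0) next
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# GFF3 (1-based, inclusive) -> internal 0-based half-open and back.
# Both conversions are exact inverses of each other.
gff_to_internal <- function(start, end) list(start = start - 1L, end = end)
internal_to_gff <- function(start, end) list(start = start + 1L, end = end)

#' Translate coding sequences with the bacterial genetic code
#'
#' Thin wrapper over [Biostrings::translate()] using translation table 11.
#' Internal stop codons appear as `*` in the output.
#'
#' @param cds character vector of in-frame nucleotide sequences.
#' @return Character vector of protein sequences.
#' @export
translate_cds <- function(cds) {
  if (length(cds) == 0) return(character(0))
  aa <- Biostrings::translate(
    Biostrings::DNAStringSet(cds),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE, if.fuzzy.codon = "X")
  out <- as.character(aa)
  names(out) <- names(cds)
  out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Construct a genome record
#'
#' The central container for one strain: its contig sequences plus gene and
#' cluster annotations in internal coordinates (0-based, half-open).
#'
#' @param strain_id strain label.
#' @param sequences named character vector of contig sequences.
#' @param genes data frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`; optional precomputed `cds`/`protein` named vectors are derived
#'   from the sequence when absent.
#' @param clusters optional data frame with columns `cluster_id`, `contig`,
#'   `start`, `end`.
#' @param cds,proteins optional named character vectors keyed by gene id.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(strain_id, sequences, genes = NULL, clusters = NULL,
                          cds = NULL, proteins = NULL) {
  stopifnot(is.character(strain_id), length(strain_id) == 1L,
            is.character(sequences), !is.null(names(sequences)))
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(0), contig = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
  }
  if (nrow(genes) > 0) {
    if (anyDuplicated(genes$gene_id))
      stop("duplicate gene ids in strain ", strain_id)
    lens <- nchar(sequences)[genes$contig]
    bad <- which(is.na(lens) | genes$start < 0 | genes$end > lens |
                   genes$end < genes$start)
    if (length(bad))
      stop("gene feature out of contig bounds: ",
           paste(genes$gene_id[bad], collapse = ", "))
  }
  if (!is.null(clusters) && nrow(clusters) > 0) {
    lens <- nchar(sequences)[clusters$contig]
    bad <- which(is.na(lens) | clusters$start < 0 | clusters$end > lens |
                   clusters$end < clusters$start)
    if (length(bad))
      stop("cluster feature out of contig bounds: ",
           paste(clusters$cluster_id[bad], collapse = ", "))
  }
  if (is.null(cds) && nrow(genes) > 0) {
    cds <- vapply(seq_len(nrow(genes)), function(i) {
      s <- substring(sequences[[genes$contig[i]]], genes$start[i] + 1L,
                     genes$end[i])
      if (identical(genes$strand[i], "-")) revcomp(s) else s
    }, "")
    names(cds) <- genes$gene_id
  }
  if (is.null(proteins) && !is.null(cds)) proteins <- translate_cds(cds)
  structure(list(strain_id = strain_id, sequences = sequences,
                 genes = genes, clusters = clusters,
                 cds = cds, proteins = proteins),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("genome_record", x$strain_id, "|", length(x$sequences), "contig(s),",
      sum(nchar(x$sequences)), "bp,", nrow(x$genes), "genes,",
      if (is.null(x$clusters)) 0 else nrow(x$clusters), "cluster(s)\n")
  invisible(x)
}

#' Parse a GFF3 annotation into internal coordinates
#'
#' GFF3 1-based inclusive `[start, end]` intervals become internal 0-based
#' half-open `[start-1, end)`. Features of type `gene` populate the gene
#' table (CDS reverse-complemented for minus-strand genes); features of
#' type `gene_cluster` populate the cluster table.
#'
#' @param path GFF3 file path or character vector of lines.
#' @param sequences named contig sequences the features refer to.
#' @param strain_id strain label for the resulting record.
#' @return A [genome_record()].
#' @export
read_gff <- function(path, sequences, strain_id = "strain") {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(genome_record(strain_id, sequences))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad)) stop("malformed GFF3 row ", bad[1])
  m <- do.call(rbind, f)
  start1 <- as.integer(m[, 4]); end1 <- as.integer(m[, 5])
  ids <- sub(".*ID=([^;]+).*", "\\1", m[, 9])
  bad <- which(end1 < start1)
  if (length(bad))
    stop("GFF3 validation error: end < start for feature ", ids[bad[1]])
  lens <- nchar(sequences)[m[, 1]]
  bad <- which(is.na(lens) | start1 < 1L | end1 > lens)
  if (length(bad))
    stop("GFF3 validation error: coordinates beyond contig for feature ",
         ids[bad[1]])
  internal <- gff_to_internal(start1, end1)
  type <- m[, 3]
  gsel <- type == "gene"
  genes <- data.frame(gene_id = ids[gsel], contig = m[gsel, 1],
                      start = internal$start[gsel], end = internal$end[gsel],
                      strand = m[gsel, 7], stringsAsFactors = FALSE)
  csel <- type == "gene_cluster"
  clusters <- if (any(csel)) {
    data.frame(cluster_id = ids[csel], contig = m[csel, 1],
               start = internal$start[csel], end = internal$end[csel],
               stringsAsFactors = FALSE)
  } else NULL
  genome_record(strain_id, sequences, genes, clusters)
}

#' Write a genome record's annotations as GFF3
#'
#' @param record a [genome_record()].
#' @param path output file.
#' @export
write_gff <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- record$genes
  if (nrow(g) > 0) {
    ext <- internal_to_gff(g$start, g$end)
    writeLines(paste(g$contig, "panclade", "gene", ext$start, ext$end, ".",
                     g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"), con)
  }
  cl <- record$clusters
  if (!is.null(cl) && nrow(cl) > 0) {
    ext <- internal_to_gff(cl$start, cl$end)
    writeLines(paste(cl$contig, "panclade", "gene_cluster", ext$start,
                     ext$end, ".", "+", ".", paste0("ID=", cl$cluster_id),
                     sep = "\t"), con)
  }
  invisible(path)
}
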