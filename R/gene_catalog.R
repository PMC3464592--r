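# Gene catalog: load, validate and filter gene models.
#
# A gene_catalog holds one row per gene (chromosome, 1-based inclusive
# coordinates, strand) plus the CDS and protein sequence of the longest
# coding form of each gene, and per-chromosome lengths.

#' Construct a gene catalog
#'
#' @param genes data.frame with columns gene_id, chromosome, start, end,
#'   strand; coordinates are 1-based inclusive (GFF3 convention).
#' @param cds named character vector of CDS sequences (names = gene_id).
#' @param protein named character vector of protein sequences.
#' @param chromosome_lengths named numeric vector, one entry per chromosome.
#' @return An object of class `gene_catalog`.
#' @export
gene_catalog <- function(genes, cds, protein, chromosome_lengths) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chromosome", "start", "end", "strand") %in%
                  names(genes)))
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  if (anyDuplicated(genes$gene_id))
    stop("gene_catalog: duplicate gene_ids: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (any(genes$start > genes$end))
    stop("gene_catalog: start > end for ",
         paste(genes$gene_id[genes$start > genes$end], collapse = ", "))
  missing_chr <- setdiff(genes$chromosome, names(chromosome_lengths))
  if (length(missing_chr))
    stop("gene_catalog: chromosomes without a length: ",
         paste(missing_chr, collapse = ", "))
  over <- genes$end > chromosome_lengths[genes$chromosome]
  if (any(over))
    stop("gene_catalog: genes extend past chromosome end: ",
         paste(genes$gene_id[over], collapse = ", "))
  miss <- setdiff(genes$gene_id, names(cds))
  if (length(miss))
    stop("gene_catalog: missing CDS for ", paste(miss, collapse = ", "))
  miss <- setdiff(genes$gene_id, names(protein))
  if (length(miss))
    stop("gene_catalog: missing protein for ", paste(miss, collapse = ", "))
  structure(list(genes = genes,
                 cds = cds[genes$gene_id],
                 protein = protein[genes$gene_id],
                 chromosome_lengths = chromosome_lengths),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("gene_catalog:", nrow(x$genes), "genes on",
      length(x$chromosome_lengths), "chromosomes\n")
  invisible(x)
}

#' Number of genes in a catalog
#' @param catalog A `gene_catalog`.
#' @export
n_genes <- function(catalog) nrow(catalog$genes)

# Validate one candidate gene record at load time. Returns NULL when the
# record must be rejected (with a warning), the cleaned record otherwise.
check_gene_record <- function(gene_id, cds, protein) {
  if (nchar(cds) %% 3 != 0) {
    warning("load_catalog: CDS of ", gene_id,
            " not divisible by 3; record rejected", call. = FALSE)
    return(NULL)
  }
  cds_nostop <- strip_stop(cds)
  prot <- sub("\\*$", "", protein)
  if (nchar(cds_nostop) != 3 * nchar(prot)) {
    warning("load_catalog: CDS/protein length mismatch for ", gene_id,
            "; record rejected", call. = FALSE)
    return(NULL)
  }
  tr <- translate_cds(cds_nostop)
  if (grepl("\\*", tr)) {
    warning("load_catalog: internal stop codon in ", gene_id,
            "; record rejected", call. = FALSE)
    return(NULL)
  }
  if (tr != prot) {
    warning("load_catalog: CDS translation does not match protein for ",
            gene_id, "; record rejected", call. = FALSE)
    return(NULL)
  }
  list(cds = cds_nostop, protein = prot)
}

#' Load a gene catalog from GFF3 plus CDS and protein FASTA
#'
#' Reads gene/mRNA/CDS features from a GFF3 file; when a gene has several
#' transcripts the longest coding form (largest summed CDS length, ties by
#' lexicographically smallest transcript id) is kept. Sequences are looked up
#' in the FASTA files by transcript id, falling back to gene id. A gene whose
#' transcript has no sequence is a hard error; a CDS whose length is not a
#' multiple of three (or that fails to translate to its protein) is rejected
#' with a warning.
#'
#' Chromosome lengths come from `##sequence-region` pragmas when present,
#' otherwise from the maximum annotated end per chromosome.
#'
#' @param gff_path,cds_fasta,protein_fasta Input paths.
#' @return A `gene_catalog`.
#' @export
load_catalog <- function(gff_path, cds_fasta, protein_fasta) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  cds_seqs <- as.character(read_fasta_dna(cds_fasta))
  prot_seqs <- as.character(read_fasta_aa(protein_fasta))
  names(cds_seqs) <- sub("\\s.*$", "", names(cds_seqs))
  names(prot_seqs) <- sub("\\s.*$", "", names(prot_seqs))

  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- sapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_)

  genes_i <- which(type == "gene")
  mrna_i <- which(type %in% c("mRNA", "transcript"))
  cds_i <- which(type == "CDS")

  # Summed CDS length per transcript.
  cds_parent <- parents[cds_i]
  cds_len <- tapply(GenomicRanges::width(gr)[cds_i], cds_parent, sum)

  rows <- list()
  cds_out <- character(0)
  prot_out <- character(0)
  for (gi in genes_i) {
    gid <- ids[gi]
    tx <- ids[mrna_i][parents[mrna_i] == gid]
    tx <- tx[tx %in% names(cds_len)]
    if (length(tx) == 0L) {
      # single-exon annotations may attach CDS directly to the gene
      if (gid %in% names(cds_len)) tx <- gid else next
    }
    lens <- cds_len[tx]
    best <- tx[order(-lens, tx)][1]
    seq_id <- if (best %in% names(cds_seqs)) best
              else if (gid %in% names(cds_seqs)) gid
              else stop("load_catalog: no CDS sequence for gene ", gid,
                        " (transcript ", best, ")")
    if (!(seq_id %in% names(prot_seqs)))
      stop("load_catalog: no protein sequence for gene ", gid,
           " (transcript ", best, ")")
    chk <- check_gene_record(gid, cds_seqs[[seq_id]], prot_seqs[[seq_id]])
    if (is.null(chk)) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gid,
      chromosome = as.character(GenomicRanges::seqnames(gr)[gi]),
      start = GenomicRanges::start(gr)[gi],
      end = GenomicRanges::end(gr)[gi],
      strand = as.character(GenomicRanges::strand(gr)[gi]),
      stringsAsFactors = FALSE)
    cds_out[gid] <- chk$cds
    prot_out[gid] <- chk$protein
  }
  if (length(rows) == 0L) stop("load_catalog: no valid genes in ", gff_path)
  genes <- do.call(rbind, rows)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"

  chrom_len <- parse_sequence_regions(gff_path)
  have <- unique(genes$chromosome)
  need <- setdiff(have, names(chrom_len))
  if (length(need)) {
    mx <- tapply(genes$end, genes$chromosome, max)
    chrom_len <- c(chrom_len, mx[need])
  }
  gene_catalog(genes, cds_out, prot_out, chrom_len[have])
}

parse_sequence_regions <- function(gff_path) {
  hdr <- grep("^##sequence-region", readLines(gff_path, warn = FALSE),
              value = TRUE)
  if (length(hdr) == 0L) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(trimws(hdr), "\\s+")
  stats::setNames(vapply(parts, function(p) as.numeric(p[4]), 0),
                  vapply(parts, function(p) p[2], ""))
}

#' Filter a gene catalog
#'
#' Drops genes on chromosomes whose name matches any of `drop_patterns`
#' (defaults target unplaced, random and mitochondrial sequences), then
#' resolves same-chromosome span overlaps by keeping, within each overlapping
#' group, the gene with the longest CDS (ties broken by lexicographically
#' smallest gene_id). Idempotent.
#'
#' @param catalog A `gene_catalog`.
#' @param drop_patterns Character vector of regular expressions matched
#'   against chromosome names.
#' @return The filtered `gene_catalog`.
#' @export
filter_catalog <- function(catalog,
                           drop_patterns = c("Un", "random", "MT", "mito")) {
  stopifnot(inherits(catalog, "gene_catalog"))
  g <- catalog$genes
  if (length(drop_patterns)) {
    bad <- Reduce(`|`, lapply(drop_patterns, function(p)
      grepl(p, g$chromosome, ignore.case = (p == "mito"))))
    g <- g[!bad, , drop = FALSE]
  }
  if (nrow(g) > 1L) {
    cdslen <- nchar(catalog$cds[g$gene_id])
    ord <- order(-cdslen, g$gene_id)
    keep <- logical(nrow(g))
    kept_by_chr <- list()
    for (i in ord) {
      chr <- g$chromosome[i]
      kept <- kept_by_chr[[chr]]
      clash <- FALSE
      if (!is.null(kept)) {
        clash <- any(g$start[i] <= g$end[kept] & g$end[i] >= g$start[kept])
      }
      if (!clash) {
        keep[i] <- TRUE
        kept_by_chr[[chr]] <- c(kept, i)
      }
    }
    g <- g[keep, , drop = FALSE]
  }
  gene_catalog(g, catalog$cds[g$gene_id], catalog$protein[g$gene_id],
               catalog$chromosome_lengths)
}

#' Write a gene catalog as GFF3 + CDS FASTA + protein FASTA
#'
#' Emits the same formats [load_catalog()] reads, so that a write/load
#' round-trip preserves every field.
#'
#' @param catalog A `gene_catalog`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the three paths written (gff, cds, protein).
#' @export
write_catalog <- function(catalog, dir, prefix = "genome") {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- catalog$genes
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     names(catalog$chromosome_lengths),
                     as.integer(catalog$chromosome_lengths)))
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    tid <- paste0(gid, ".t1")
    lines <- c(lines,
      sprintf("%s\tdupscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chromosome[i], g$start[i], g$end[i], g$strand[i], gid),
      sprintf("%s\tdupscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chromosome[i], g$start[i], g$end[i], g$strand[i], tid, gid),
      sprintf("%s\tdupscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
              g$chromosome[i], g$start[i],
              g$start[i] + nchar(catalog$cds[[gid]]) - 1L,
              g$strand[i], tid, tid))
  }
  writeLines(lines, gff)
  cds_path <- file.path(dir, paste0(prefix, ".cds.fa"))
  prot_path <- file.path(dir, paste0(prefix, ".pep.fa"))
  cds <- catalog$cds
  prot <- catalog$protein
  names(cds) <- names(prot) <- paste0(g$gene_id, ".t1")
  write_fasta(cds, cds_path)
  write_fasta(prot, prot_path)
  invisible(c(gff = gff, cds = cds_path, protein = prot_path))
}
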