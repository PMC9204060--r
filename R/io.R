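# Readers and writers for the standard formats the pipeline touches.
#
# Sequences travel as tibbles with columns `id`, `seq`, `desc`; annotation as a
# feature tibble in 0-based half-open internal coordinates; expression as a wide
# tibble (feature_id + one numeric column per sample) with a sample-metadata
# sidecar. Parsing of FASTA/FASTQ is delegated to Biostrings and GFF3 to
# rtracklayer; this module owns validation and the coordinate convention.

SEQ_ALPHABET <- c("A", "C", "G", "U", "T", "N")

validate_seq_records <- function(seqs, what = "sequence") {
  if (nrow(seqs) == 0) abort(paste0("empty ", what, " set"))
  if (any(!nzchar(seqs$id))) abort("sequence ids must be non-empty")
  dup <- seqs$id[duplicated(seqs$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence id(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (any(!nzchar(seqs$seq))) {
    abort(paste0("empty sequence for id(s): ",
                 paste(seqs$id[!nzchar(seqs$seq)], collapse = ", ")))
  }
  bad <- grepl(paste0("[^", paste(SEQ_ALPHABET, collapse = ""), "]"), seqs$seq)
  if (any(bad)) {
    abort(paste0("sequence contains letters outside {A,C,G,U,T,N}: ",
                 paste(seqs$id[bad], collapse = ", ")))
  }
  invisible(seqs)
}

#' Read a FASTA file into a sequence tibble
#'
#' Sequences are uppercased on input. With `rna = TRUE` all `T` are normalised
#' to `U`, the convention used by every duplex operation in the target engine;
#' FASTA output written by [write_fasta()] preserves whatever alphabet the
#' tibble holds.
#'
#' @param path Path to a FASTA file.
#' @param rna Normalise `T` to `U` (RNA mode)?
#' @return A tibble with columns `id`, `seq`, `desc`. Ids must be unique and
#'   sequences non-empty, otherwise an error names the offending record.
#' @export
read_fasta <- function(path, rna = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) abort(paste0("empty FASTA file: ", path))
  headers <- names(ss)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq <- toupper(as.character(ss))
  if (rna) seq <- chartr("T", "U", seq)
  out <- tibble(id = id, seq = unname(seq), desc = desc)
  validate_seq_records(out)
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id`, `seq` and optionally `desc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_tibble(seqs)
  if (!"desc" %in% names(seqs)) seqs$desc <- ""
  validate_seq_records(seqs)
  ss <- Biostrings::BStringSet(seqs$seq)
  names(ss) <- ifelse(nzchar(seqs$desc), paste(seqs$id, seqs$desc), seqs$id)
  Biostrings::writeXStringSet(ss, path, format = "fasta")
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path Path to a FASTQ file (Phred+33 qualities).
#' @return A tibble with columns `id`, `seq`, `qual` where
#'   `nchar(seq) == nchar(qual)` for every read.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(ss)$qualities)
  tibble(
    id = sub("\\s.*$", "", names(ss)),
    seq = unname(as.character(ss)),
    qual = unname(qual)
  )
}

#' Write a read tibble to FASTQ
#'
#' @param reads Tibble with columns `id`, `seq`, `qual` (Phred+33).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  ss <- Biostrings::DNAStringSet(chartr("U", "T", toupper(reads$seq)))
  names(ss) <- reads$id
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

# Annotation -------------------------------------------------------------

ANNOT_COLS <- c("seqid", "type", "start", "end", "strand", "id", "parent", "biotype")

#' Validate an annotation tibble
#'
#' Internal coordinates are 0-based half-open, so `start < end` and every exon
#' lies within its parent transcript's span. Strand must be `+` or `-`.
#'
#' @param annot Annotation tibble with columns `seqid`, `type`, `start`, `end`,
#'   `strand`, `id`, `parent`, `biotype`.
#' @return `annot`, invisibly, or an error describing the violated invariant.
#' @export
validate_annotation <- function(annot) {
  missing <- setdiff(ANNOT_COLS, names(annot))
  if (length(missing) > 0) {
    abort(paste0("annotation lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(!annot$strand %in% c("+", "-"))) {
    bad <- unique(annot$strand[!annot$strand %in% c("+", "-")])
    abort(paste0("unknown strand symbol(s): ", paste(bad, collapse = ", ")))
  }
  if (any(annot$start >= annot$end)) {
    abort("malformed interval: start must be < end (0-based half-open)")
  }
  tx <- filter(annot, .data$type == "transcript")
  ex <- filter(annot, .data$type == "exon")
  if (nrow(ex) > 0) {
    span <- tx %>% select(parent_id = "id", tx_start = "start", tx_end = "end")
    chk <- left_join(ex, span, by = c(parent = "parent_id"))
    out_of_span <- is.na(chk$tx_start) | chk$start < chk$tx_start | chk$end > chk$tx_end
    if (any(out_of_span)) {
      abort(paste0("exon outside its transcript span (or orphan exon): ",
                   paste(head(chk$id[out_of_span], 5), collapse = ", ")))
    }
  }
  invisible(annot)
}

# GFF3 prints 1-based inclusive coordinates; internally we keep 0-based
# half-open intervals. The two helpers below are inverses of one another.
gff_to_internal <- function(start, end) list(start = start - 1L, end = end)
internal_to_gff <- function(start, end) list(start = start + 1L, end = end)

#' Read a GFF3 annotation
#'
#' Converts the printed 1-based inclusive coordinates to the package's
#' internal 0-based half-open convention, preserves strand, and reads the
#' transcript biotype from the attributes column.
#'
#' @param path Path to a GFF3 file with gene/transcript/exon rows.
#' @return A validated annotation tibble (see [validate_annotation()]).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% names(md)) {
    vapply(as.list(md$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else {
    rep(NA_character_, length(gr))
  }
  biotype <- if ("biotype" %in% names(md)) as.character(md$biotype) else rep(NA_character_, length(gr))
  coords <- gff_to_internal(BiocGenerics::start(gr), BiocGenerics::end(gr))
  out <- tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(md$type),
    start = as.integer(coords$start),
    end = as.integer(coords$end),
    strand = as.character(BiocGenerics::strand(gr)),
    id = as.character(md$ID),
    parent = parent,
    biotype = biotype
  )
  validate_annotation(out)
  out
}

#' Write an annotation tibble to GFF3
#'
#' The inverse of [read_gff3()]: internal 0-based half-open intervals are
#' printed back as 1-based inclusive GFF3 coordinates, so a write/read round
#' trip restores the annotation exactly.
#'
#' @param annot Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annot, path) {
  validate_annotation(annot)
  coords <- internal_to_gff(annot$start, annot$end)
  gr <- GenomicRanges::GRanges(
    seqnames = annot$seqid,
    ranges = IRanges::IRanges(start = coords$start, end = coords$end),
    strand = annot$strand
  )
  md <- S4Vectors::DataFrame(
    source = rep("cernaforge", nrow(annot)),
    type = annot$type,
    ID = annot$id,
    biotype = annot$biotype
  )
  md$Parent <- ifelse(is.na(annot$parent), "", annot$parent)
  S4Vectors::mcols(gr) <- md
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# Expression matrices ----------------------------------------------------

#' Read a gene-by-sample expression matrix with its sample metadata
#'
#' The matrix is a TSV whose first column holds feature ids and whose header
#' row holds sample ids; the sidecar maps each sample id to its genotype
#' (`wild`/`mutant`), leaf position (`flag`/`second`/`third`) and replicate.
#' Samples without metadata are rejected, as are negative or non-numeric
#' cells (the error names the offending row and column).
#'
#' @param path Path to the expression TSV.
#' @param metadata_path Path to the sample-metadata TSV.
#' @return A list with elements `expr` (wide tibble) and `samples` (tibble).
#' @export
read_expression <- function(path, metadata_path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  samples <- readr::read_tsv(metadata_path, show_col_types = FALSE, progress = FALSE)
  validate_expression(expr)
  check_samples(expr, samples)
  list(expr = expr, samples = samples)
}

validate_expression <- function(expr) {
  if (ncol(expr) < 2) abort("expression table needs a feature column and >= 1 sample")
  for (j in seq(2, ncol(expr))) {
    col <- expr[[j]]
    if (!is.numeric(col)) {
      abort(paste0("non-numeric cell(s) in column '", names(expr)[j], "'"))
    }
    if (anyNA(col)) {
      abort(paste0("missing/unparsable cell in column '", names(expr)[j],
                   "', row ", which(is.na(col))[1]))
    }
    if (any(col < 0)) {
      abort(paste0("negative value in column '", names(expr)[j], "', row ",
                   which(col < 0)[1], " (feature ", expr[[1]][which(col < 0)[1]], ")"))
    }
  }
  invisible(expr)
}

#' Write an expression matrix and sample metadata to TSV
#'
#' @param expr Wide expression tibble (feature column first).
#' @param samples Sample-metadata tibble.
#' @param path,metadata_path Output paths.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, samples, path, metadata_path) {
  validate_expression(expr)
  readr::write_tsv(expr, path)
  readr::write_tsv(samples, metadata_path)
  invisible(path)
}

#' Read a term-to-gene annotation map
#'
#' @param path TSV with columns `term` and `gene`.
#' @return A tibble with columns `term`, `gene`.
#' @export
read_term_map <- function(path) {
  tm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("term", "gene") %in% names(tm))) {
    abort("term map must have columns 'term' and 'gene'")
  }
  distinct(tm, .data$term, .data$gene)
}
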