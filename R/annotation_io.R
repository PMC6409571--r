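#' Read genome sequences from a FASTA file
#'
#' Each FASTA record becomes one genome record. The genome identifier is the
#' first whitespace-delimited word of the header line. GC fraction is
#' computed as (G+C)/(A+C+G+T); ambiguous bases are excluded from both
#' numerator and denominator.
#'
#' @param path Path to a FASTA file of genome (or replicon) sequences.
#' @param circular Logical, recycled across records; NCBI viral FASTA does
#'   not encode topology, so the default is linear.
#' @return A data.frame with columns `genome_id`, `length_bp`,
#'   `gc_fraction`, `circular`, carrying the sequences as a
#'   [Biostrings::DNAStringSet] in attribute `"sequences"` (see
#'   [genome_sequences()]).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", "ACGT"), fa)
#' g <- read_genome_fasta(fa)
#' g$gc_fraction  # 0.5
read_genome_fasta <- function(path, circular = FALSE) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("no sequences found in ", path)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate genome identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(seqs) <- ids
  freq <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  unambig <- rowSums(freq)
  gcf <- ifelse(unambig > 0, (freq[, "G"] + freq[, "C"]) / unambig, NA_real_)
  out <- data.frame(
    genome_id = ids,
    length_bp = Biostrings::width(seqs),
    gc_fraction = as.numeric(gcf),
    circular = rep_len(circular, length(seqs)),
    stringsAsFactors = FALSE
  )
  attr(out, "sequences") <- seqs
  out
}

#' Retrieve the sequences attached to a genome table
#'
#' @param genomes A data.frame returned by [read_genome_fasta()].
#' @return A [Biostrings::DNAStringSet] named by genome identifier.
#' @export
genome_sequences <- function(genomes) {
  seqs <- attr(genomes, "sequences")
  if (is.null(seqs)) stop("genome table carries no sequences")
  seqs
}

#' Read tRNA gene annotations
#'
#' Parses tRNA gene annotations into the internal model: 0-based half-open
#' coordinates, single-letter isotypes over the 23-symbol alphabet (20
#' standard amino acids, O = pyrrolysine, U = selenocysteine,
#' X = undetermined), DNA anticodons.
#'
#' Dialects:
#' \describe{
#'   \item{`trnascan_tsv`}{tRNAscan-SE 2.0 tabular output (columns: sequence
#'     name, tRNA number, begin, end, type, anticodon, intron begin/end,
#'     score). Coordinates are 1-based inclusive; rows with begin > end are
#'     minus-strand genes and are swapped.}
#'   \item{`gff3`}{GFF3 features of type `tRNA`; the isotype is taken from a
#'     `product` attribute of the form `tRNA-Xxx`, the anticodon from an
#'     `anticodon` attribute when present.}
#'   \item{`simple_tsv`}{the package's own TSV (genome_id, start, end,
#'     strand, isotype, anticodon) already in internal coordinates, as
#'     written by [write_report()].}
#' }
#'
#' Unknown three-letter isotype names map to X with a warning. tRNA gene
#' lengths outside 50--200 bp raise a warning, not an error.
#'
#' @param path Path to the annotation file.
#' @param dialect One of `"trnascan_tsv"`, `"gff3"`, `"simple_tsv"`.
#' @return A data.frame with columns `genome_id`, `start`, `end`, `strand`,
#'   `isotype`, `anticodon`, sorted by genome_id then start.
#' @export
read_trna_annotations <- function(path,
                                  dialect = c("trnascan_tsv", "gff3",
                                              "simple_tsv")) {
  dialect <- match.arg(dialect)
  out <- switch(dialect,
    trnascan_tsv = parse_trnascan(path),
    gff3 = parse_trna_gff3(path),
    simple_tsv = parse_trna_simple(path)
  )
  validate_trna_genes(out)
  out[order(out$genome_id, out$start), , drop = FALSE]
}

parse_trnascan <- function(path) {
  lines <- readLines(path)
  is_header <- grepl("^(Sequence|Name|-{2,})", lines) |
    grepl("^\\s*$", lines)
  body_idx <- which(!is_header)
  if (length(body_idx) == 0L) {
    return(empty_trna_table())
  }
  rows <- lapply(body_idx, function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 6L || is.na(suppressWarnings(as.numeric(f[3]))) ||
        is.na(suppressWarnings(as.numeric(f[4])))) {
      stop("malformed tRNAscan-SE row at line ", i, " of ", path)
    }
    b <- as.integer(f[3]); e <- as.integer(f[4])
    data.frame(
      genome_id = f[1],
      start = min(b, e) - 1L,
      end = max(b, e),
      strand = if (b <= e) "+" else "-",
      isotype = map_isotype(f[5]),
      anticodon = normalize_anticodon(f[6]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

parse_trna_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "tRNA"]
  if (length(gr) == 0L) {
    return(empty_trna_table())
  }
  mc <- S4Vectors::mcols(gr)
  product <- if ("product" %in% names(mc)) as.character(mc$product)
             else rep(NA_character_, length(gr))
  iso <- vapply(product, isotype_from_product, character(1), USE.NAMES = FALSE)
  anti <- if ("anticodon" %in% names(mc)) {
    vapply(as.character(mc$anticodon), normalize_anticodon, character(1),
           USE.NAMES = FALSE)
  } else {
    rep(NA_character_, length(gr))
  }
  data.frame(
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    isotype = iso,
    anticodon = anti,
    stringsAsFactors = FALSE
  )
}

parse_trna_simple <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(genome_id = "character",
                                  isotype = "character",
                                  anticodon = "character",
                                  strand = "character"))
  need <- c("genome_id", "start", "end", "strand", "isotype", "anticodon")
  if (!all(need %in% names(df))) {
    stop("simple tRNA TSV must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$anticodon[df$anticodon %in% c("", "NA")] <- NA_character_
  df
}

empty_trna_table <- function() {
  data.frame(genome_id = character(), start = integer(), end = integer(),
             strand = character(), isotype = character(),
             anticodon = character(), stringsAsFactors = FALSE)
}

# Map a predictor's isotype label (3-letter name or single letter) to the
# internal single-letter code; unknown labels become X with a warning.
map_isotype <- function(label) {
  label <- trimws(label)
  if (label %in% names(AA3_TO_1)) return(unname(AA3_TO_1[label]))
  if (nchar(label) == 1L && toupper(label) %in% ISOTYPE_ALPHABET) {
    return(toupper(label))
  }
  warning("unknown isotype label '", label, "' mapped to X", call. = FALSE)
  "X"
}

isotype_from_product <- function(product) {
  if (is.na(product)) return("X")
  m <- regmatches(product, regexpr("tRNA-([A-Za-z0-9]+)", product))
  if (length(m) == 0L) return(map_isotype(product))
  map_isotype(sub("^tRNA-", "", m))
}

# Uppercase, RNA->DNA; unknown placeholders become NA.
normalize_anticodon <- function(ac) {
  if (is.na(ac)) return(NA_character_)
  ac <- chartr("u", "U", toupper(trimws(ac)))
  ac <- chartr("U", "T", ac)
  if (!grepl("^[ACGT]{3}$", ac)) return(NA_character_)
  ac
}

validate_trna_genes <- function(genes) {
  if (nrow(genes) == 0L) return(invisible(genes))
  if (any(genes$start >= genes$end)) {
    stop("tRNA gene with start >= end")
  }
  bad <- !genes$isotype %in% ISOTYPE_ALPHABET
  if (any(bad)) {
    stop("isotype outside alphabet: ",
         paste(unique(genes$isotype[bad]), collapse = ", "))
  }
  len <- genes$end - genes$start
  odd <- len < 50L | len > 200L
  if (any(odd)) {
    warning(sum(odd), " tRNA gene(s) with length outside 50-200 bp",
            call. = FALSE)
  }
  invisible(genes)
}

#' Read CDS annotations
#'
#' For GFF3 input, CDS sequences are extracted from the genome sequences and
#' minus-strand features are reverse-complemented, so `sequence` is always
#' the coding strand 5'->3'. For FASTA input the records are taken to be
#' coding-strand CDS sequences already (coordinates are then unknown).
#' Sequences whose length is not divisible by 3 are trimmed of the trailing
#' incomplete codon with a warning.
#'
#' @param path Path to a GFF3 file with `CDS` features or a FASTA of CDS
#'   nucleotide sequences.
#' @param genomes Genome table from [read_genome_fasta()] (required for
#'   GFF3).
#' @param dialect `"gff3"` or `"fasta"`.
#' @return A data.frame with columns `genome_id`, `cds_id`, `start`, `end`,
#'   `strand`, `product`, `sequence`.
#' @export
read_cds <- function(path, genomes = NULL, dialect = c("gff3", "fasta")) {
  dialect <- match.arg(dialect)
  if (dialect == "fasta") {
    seqs <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(seqs))
    desc <- sub("^\\S+\\s*", "", names(seqs))
    out <- data.frame(
      genome_id = NA_character_, cds_id = ids,
      start = NA_integer_, end = NA_integer_, strand = "+",
      product = ifelse(nzchar(desc), desc, NA_character_),
      sequence = as.character(seqs),
      stringsAsFactors = FALSE
    )
    return(trim_cds_frames(out))
  }
  if (is.null(genomes)) stop("GFF3 CDS input requires the genome table")
  seqs <- genome_sequences(genomes)
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  mc <- S4Vectors::mcols(gr)
  gid <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(gid, names(seqs))
  if (length(unknown)) {
    stop("CDS reference sequence(s) not in genome set: ",
         paste(unknown, collapse = ", "))
  }
  s1 <- GenomicRanges::start(gr)
  e1 <- GenomicRanges::end(gr)
  too_long <- e1 > Biostrings::width(seqs)[match(gid, names(seqs))]
  if (any(too_long)) {
    stop("CDS coordinates exceed genome length for: ",
         paste(unique(gid[too_long]), collapse = ", "))
  }
  strand <- ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+")
  seq_chr <- vapply(seq_along(gr), function(i) {
    s <- Biostrings::subseq(seqs[[gid[i]]], start = s1[i], end = e1[i])
    if (strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID)
         else sprintf("%s_cds%04d", gid, seq_along(gr))
  product <- if ("product" %in% names(mc)) as.character(mc$product)
             else rep(NA_character_, length(gr))
  out <- data.frame(
    genome_id = gid, cds_id = ids,
    start = s1 - 1L, end = e1, strand = strand,
    product = product, sequence = seq_chr,
    stringsAsFactors = FALSE
  )
  trim_cds_frames(out)
}

trim_cds_frames <- function(cds) {
  if (nrow(cds) == 0L) return(cds)
  len <- nchar(cds$sequence)
  rem <- len %% 3L
  if (any(rem > 0L)) {
    warning(sum(rem > 0L),
            " CDS sequence(s) trimmed of a trailing incomplete codon",
            call. = FALSE)
    cds$sequence <- substr(cds$sequence, 1L, len - rem)
  }
  short <- nchar(cds$sequence) < 3L
  if (any(short)) {
    stop("CDS sequence shorter than one codon: ",
         paste(cds$cds_id[short], collapse = ", "))
  }
  cds
}

#' Write a report table as tab-separated text
#'
#' Writes a header row and tab-separated fields, UTF-8, with a deterministic
#' row order (sorted by `genome_id` then `start` when those columns are
#' present). List-columns (such as cluster members) are dropped. A field
#' containing a tab is an error, so that read-back is unambiguous.
#'
#' @param table A data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(table, path) {
  keep <- !vapply(table, is.list, logical(1))
  table <- table[, keep, drop = FALSE]
  chr <- vapply(table, is.character, logical(1))
  for (cn in names(table)[chr]) {
    if (any(grepl("\t", table[[cn]], fixed = TRUE), na.rm = TRUE)) {
      stop("field '", cn, "' contains a tab character")
    }
  }
  ord <- intersect(c("genome_id", "start", "span_start"), names(table))
  if (length(ord)) {
    table <- table[do.call(order, table[ord]), , drop = FALSE]
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Path to a TSV report.
#' @return A data.frame.
#' @export
read_report <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
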