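#' Read a multi-record FASTA file
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sequences)) {
    writeLines(paste0(">", nm), con)
    s <- sequences[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Normalise a nucleotide string to the RNA alphabet
#'
#' Upper-cases and maps T to U. Characters outside `{A,C,G,U,N}` raise an
#' error: downstream pattern scanners assume this alphabet, and `N` never
#' matches any pattern class.
#'
#' @param x Character vector of sequences.
#' @return Character vector over `{A,C,G,U,N}`.
#' @export
as_rna <- function(x) {
  out <- chartr("Tt", "Uu", toupper(x))
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    stop("sequence contains characters outside the {A,C,G,U/T,N} alphabet")
  }
  out
}

#' Reverse complement of an RNA string
#'
#' @param x RNA string(s) over `{A,C,G,U,N}`.
#' @return Reverse complement, same alphabet.
#' @export
rna_revcomp <- function(x) {
  comp <- chartr("ACGUN", "UGCAN", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

#' Extract the transcribed-strand (sense) sequence of an interval
#'
#' Returns the RNA-alphabet sequence that the transcription machinery
#' would produce from the interval: the plus-strand slice for `+`, its
#' reverse complement for `-`, with `T` mapped to `U` in both cases.
#'
#' @param genome Named character vector from [read_fasta()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open genomic interval.
#' @param strand `"+"` or `"-"` (unstranded treated as `+`).
#' @return Single RNA string.
#' @export
extract_sense_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    stop("chromosome not found in genome: ", chrom)
  }
  n <- nchar(genome[[chrom]])
  if (start < 0L || end > n || start >= end) {
    stop("interval [", start, ",", end, ") out of bounds for ", chrom,
         " (length ", n, ")")
  }
  s <- as_rna(substr(genome[[chrom]], start + 1L, end))
  if (identical(strand, "-")) s <- rna_revcomp(s)
  s
}

# ---- transcript models -----------------------------------------------------

new_transcript_model <- function(transcript_id, gene_id, chrom, strand,
                                 exons, cds_segments) {
  exons <- dplyr::arrange(exons, .data$start)
  widths <- exons$end - exons$start
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  tx_length <- sum(widths)
  introns <- if (nrow(exons) > 1L) {
    tibble::tibble(chrom = chrom,
                   start = exons$end[-nrow(exons)],
                   end = exons$start[-1L],
                   strand = strand)
  } else {
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   strand = character())
  }

  cds_span <- NULL
  regions <- NULL
  if (!is.null(cds_segments) && nrow(cds_segments) > 0L) {
    # every CDS segment must lie within one exon
    inside <- vapply(seq_len(nrow(cds_segments)), function(i) {
      any(cds_segments$start[i] >= exons$start &
            cds_segments$end[i] <= exons$end)
    }, logical(1))
    if (!all(inside)) {
      stop("CDS outside exons in transcript ", transcript_id)
    }
    cds_span <- c(min(cds_segments$start), max(cds_segments$end))
    t_lo <- genomic_to_transcript(cds_span[1], exons, strand,
                                  tx_length)
    t_hi <- genomic_to_transcript(cds_span[2] - 1L, exons, strand,
                                  tx_length)
    cds_t <- sort(c(t_lo, t_hi))
    cds_t[2] <- cds_t[2] + 1L
    regions <- tibble::tibble(
      region = c("5'UTR", "CDS", "3'UTR"),
      start = c(0L, cds_t[1], cds_t[2]),
      end = c(cds_t[1], cds_t[2], tx_length)
    )
    regions <- regions[regions$end > regions$start, , drop = FALSE]
  }

  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 cds_span = cds_span, tx_length = tx_length,
                 regions = regions, introns = introns),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model>", x$transcript_id, "gene", x$gene_id, "on",
      x$chrom, x$strand, "\n  ", nrow(x$exons), "exon(s),",
      x$tx_length, "nt mature transcript",
      if (is.null(x$cds_span)) "(noncoding)" else "", "\n")
  invisible(x)
}

# map a genomic position (0-based) to its transcript coordinate
genomic_to_transcript <- function(pos, exons, strand, tx_length) {
  widths <- exons$end - exons$start
  idx <- which(pos >= exons$start & pos < exons$end)
  if (length(idx) != 1L) stop("position ", pos, " is not exonic")
  before <- if (idx > 1L) sum(widths[seq_len(idx - 1L)]) else 0L
  t_plus <- before + (pos - exons$start[idx])
  if (identical(strand, "-")) tx_length - 1L - t_plus else t_plus
}

#' Region length summary of a transcript model
#'
#' @param model A `transcript_model`.
#' @return Named integer vector of 5'UTR, CDS, 3'UTR lengths (zeros when
#'   absent) plus intron total.
#' @export
region_lengths <- function(model) {
  out <- c("5'UTR" = 0L, CDS = 0L, "3'UTR" = 0L, intron = 0L)
  if (!is.null(model$regions)) {
    len <- model$regions$end - model$regions$start
    out[model$regions$region] <- len
  }
  out["intron"] <- sum(model$introns$end - model$introns$start)
  out
}

#' Genomic footprint of transcript regions
#'
#' Splits the exons of a coding transcript into genomic 5'UTR/CDS/3'UTR
#' pieces (strand-aware); noncoding transcripts yield `ncRNA` exon pieces.
#' Introns are included with label `intron`.
#'
#' @param model A `transcript_model`.
#' @return Tibble with `chrom`, `start`, `end`, `region`.
#' @export
region_genomic_intervals <- function(model) {
  exons <- model$exons
  pieces <- if (is.null(model$cds_span)) {
    tibble::tibble(chrom = model$chrom, start = exons$start,
                   end = exons$end, region = "ncRNA")
  } else {
    cs <- model$cds_span[1]
    ce <- model$cds_span[2]
    res <- list()
    for (i in seq_len(nrow(exons))) {
      es <- exons$start[i]; ee <- exons$end[i]
      cuts <- sort(unique(pmax(es, pmin(ee, c(es, cs, ce, ee)))))
      for (j in seq_len(length(cuts) - 1L)) {
        a <- cuts[j]; b <- cuts[j + 1L]
        if (b <= a) next
        lab <- if (b <= cs) {
          if (model$strand == "+") "5'UTR" else "3'UTR"
        } else if (a >= ce) {
          if (model$strand == "+") "3'UTR" else "5'UTR"
        } else "CDS"
        res[[length(res) + 1L]] <- tibble::tibble(
          chrom = model$chrom, start = a, end = b, region = lab)
      }
    }
    dplyr::bind_rows(res)
  }
  if (nrow(model$introns) > 0L) {
    pieces <- dplyr::bind_rows(
      pieces,
      tibble::tibble(chrom = model$chrom, start = model$introns$start,
                     end = model$introns$end, region = "intron"))
  }
  dplyr::arrange(pieces, .data$start)
}

#' Read transcript models from a GTF/GFF annotation
#'
#' File coordinates (1-based, closed) are converted to the package's
#' 0-based half-open convention. Models whose CDS falls outside their
#' exons are rejected with a warning naming the transcript.
#'
#' @param path GTF/GFF file with `exon` and `CDS` features carrying
#'   `gene_id` and `transcript_id` attributes.
#' @return Named list of `transcript_model` objects.
#' @export
read_transcript_models <- function(path) {
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("failed to parse annotation ",
                                          path, ": ", conditionMessage(e)))
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id))
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(df) == 0L) stop("no exon/CDS features found in ", path)

  models <- list()
  rejected <- character()
  for (tx in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == tx, , drop = FALSE]
    exons <- sub[sub$type == "exon", c("start", "end"), drop = FALSE]
    cds <- sub[sub$type == "CDS", c("start", "end"), drop = FALSE]
    m <- tryCatch(
      new_transcript_model(tx, sub$gene_id[1], sub$chrom[1], sub$strand[1],
                           tibble::as_tibble(exons),
                           if (nrow(cds)) tibble::as_tibble(cds) else NULL),
      error = function(e) conditionMessage(e))
    if (is.character(m)) rejected <- c(rejected, paste0(tx, ": ", m))
    else models[[tx]] <- m
  }
  if (length(rejected)) {
    warning("rejected ", length(rejected), " transcript model(s):\n  ",
            paste(rejected, collapse = "\n  "))
  }
  models
}

#' Mature (spliced) transcript sequence
#'
#' @param model A `transcript_model`.
#' @param genome Named character vector from [read_fasta()].
#' @return RNA string in transcript (5' to 3') orientation.
#' @export
transcript_sequence <- function(model, genome) {
  parts <- vapply(seq_len(nrow(model$exons)), function(i) {
    extract_sense_sequence(genome, model$chrom, model$exons$start[i],
                           model$exons$end[i], model$strand)
  }, "")
  if (model$strand == "-") parts <- rev(parts)
  paste(parts, collapse = "")
}

# ---- BED / bedGraph / TSV --------------------------------------------------

#' Write intervals as BED6
#'
#' @param x Tibble with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand`.
#' @param path Output file.
#' @export
write_bed <- function(x, path) {
  out <- data.frame(
    chrom = x$chrom, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = if ("strand" %in% names(x)) x$strand else "*")
  out$strand[out$strand == "*"] <- "."
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file into the internal interval convention
#'
#' @param path BED file (3-6 columns).
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (is.null(gr$name)) rep(".", length(gr)) else gr$name,
    score = if (is.null(gr$score)) rep(0, length(gr)) else as.numeric(gr$score),
    strand = chartr(".", "*", as.character(GenomicRanges::strand(gr))))
}

#' Write a coverage track as bedGraph
#'
#' @param track Tibble with `chrom`, `start`, `end`, `value`.
#' @param path Output file.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open
#'   as in the format definition).
#' @return Tibble with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score))
  if (any(out$value < 0)) stop("negative coverage in ", path)
  out
}

#' Write transcript models to GTF
#'
#' Inverse of [read_transcript_models()]: emits `exon` and `CDS` features
#' in 1-based closed GTF coordinates.
#'
#' @param models Named list of `transcript_model` objects.
#' @param path Output file.
#' @export
write_gtf <- function(models, path) {
  lines <- character()
  for (m in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', m$gene_id,
                     m$transcript_id)
    ex <- sprintf("%s\tquadte\texon\t%d\t%d\t.\t%s\t.\t%s",
                  m$chrom, m$exons$start + 1L, m$exons$end, m$strand, attrs)
    lines <- c(lines, ex)
    if (!is.null(m$cds_span)) {
      # clip CDS span to exons to emit per-exon CDS segments
      cs <- m$cds_span[1]; ce <- m$cds_span[2]
      keep <- m$exons$end > cs & m$exons$start < ce
      s <- pmax(m$exons$start[keep], cs)
      e <- pmin(m$exons$end[keep], ce)
      lines <- c(lines, sprintf("%s\tquadte\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                m$chrom, s + 1L, e, m$strand, attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a polysome-profiling FPKM table
#'
#' Expects a TSV with a header and columns `gene_id` plus
#' `fpkm_<fraction>_<condition>_<rep>` for fraction in `total`,
#' `polysome`, condition in `ctrl`, `ko`, rep in `1`, `2`.
#'
#' @param path TSV file.
#' @return Tibble with the nine required columns.
#' @export
read_fpkm_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("gene_id", fpkm_columns())
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("FPKM table is missing column(s): ", paste(missing, collapse = ", "))
  }
  tab
}

fpkm_columns <- function() {
  as.vector(outer(
    c("fpkm_total", "fpkm_polysome"),
    as.vector(outer(c("ctrl", "ko"), c("1", "2"), paste, sep = "_")),
    paste, sep = "_"))
}
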