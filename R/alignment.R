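#' Multi-species alignment block
#'
#' An alignment block holds equal-length aligned sequences for several
#' species, anchored to a reference genome interval. The reference row may
#' contain gap columns (insertions in other species); its gap-free length
#' defines the reference span. Coordinates are 0-based, half-open.
#'
#' @param rows Named character vector of aligned sequences over
#'   \code{A,C,G,T,N,-} (case-insensitive); names are species identifiers.
#' @param ref_species Species whose row anchors reference coordinates;
#'   defaults to the first row.
#' @param ref_chrom Reference chromosome name.
#' @param ref_start 0-based reference start coordinate of the block.
#' @param ref_strand Reference strand, \code{"+"} or \code{"-"}.
#' @return An object of class \code{alignment_block}.
#' @examples
#' blk <- alignment_block(c(mouse = "GGTAATCCAA", rat = "GGTAATCCAA"))
#' ref_sequence(blk)
#' @export
alignment_block <- function(rows, ref_species = names(rows)[1],
                            ref_chrom = "chr1", ref_start = 0L,
                            ref_strand = "+") {
  if (is.null(names(rows)) || anyNA(names(rows)) || any(names(rows) == ""))
    stop("all rows must be named with a species identifier")
  if (anyDuplicated(names(rows)))
    stop("species identifiers must be unique within a block")
  rows <- toupper(vapply(rows, as.character, character(1)))
  if (length(unique(nchar(rows))) != 1L)
    stop("all aligned sequences must have the same column count")
  bad <- grepl("[^ACGTN-]", rows)
  if (any(bad))
    stop("alignment rows may only contain A, C, G, T, N or '-': ",
         paste(names(rows)[bad], collapse = ", "))
  if (!ref_species %in% names(rows))
    stop("reference species '", ref_species, "' not among rows")
  if (!ref_strand %in% c("+", "-")) stop("ref_strand must be '+' or '-'")
  structure(
    list(rows = rows, ref_species = ref_species, ref_chrom = ref_chrom,
         ref_start = as.integer(ref_start), ref_strand = ref_strand),
    class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("alignment_block: %d species, %d columns, %s:%d-%d (%s, ref %s)\n",
              length(x$rows), nchar(x$rows[[1]]), x$ref_chrom, x$ref_start,
              x$ref_start + nchar(ref_sequence(x)), x$ref_strand,
              x$ref_species))
  invisible(x)
}

#' Gap-free reference sequence of an alignment block
#'
#' @param block An \code{alignment_block}.
#' @return Character scalar: the reference row with gap columns removed.
#' @export
ref_sequence <- function(block) {
  stopifnot(inherits(block, "alignment_block"))
  gsub("-", "", block$rows[[block$ref_species]], fixed = TRUE)
}

#' Reverse-complement an alignment block
#'
#' Reverse-complements every row (gaps preserved) and reverses the column
#' order, so a motif at reference coordinates \code{[s, e)} on the plus
#' strand maps to \code{[L - e, L - s)} on the minus strand, where \code{L}
#' is the reference span. Used mainly for strand-symmetry checks.
#'
#' @param block An \code{alignment_block}.
#' @return A new \code{alignment_block}.
#' @export
revcomp_block <- function(block) {
  stopifnot(inherits(block, "alignment_block"))
  rc <- vapply(block$rows, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1))
  alignment_block(rc, ref_species = block$ref_species,
                  ref_chrom = block$ref_chrom, ref_start = block$ref_start,
                  ref_strand = if (block$ref_strand == "+") "-" else "+")
}

#' Read an aligned multi-FASTA file as an alignment block
#'
#' All records must be the same aligned length; the reference defaults to
#' the first record.
#'
#' @param file Path to an aligned FASTA file (gaps as \code{-}).
#' @param ref_species Reference species name; default first record.
#' @param ref_chrom,ref_start Reference anchoring (see
#'   \code{\link{alignment_block}}).
#' @return An \code{alignment_block}.
#' @export
read_aligned_fasta <- function(file, ref_species = NULL, ref_chrom = "chr1",
                               ref_start = 0L) {
  ss <- Biostrings::readBStringSet(file)
  rows <- as.character(ss)
  names(rows) <- sub("\\s.*$", "", names(ss))
  if (is.null(ref_species)) ref_species <- names(rows)[1]
  alignment_block(rows, ref_species = ref_species, ref_chrom = ref_chrom,
                  ref_start = ref_start)
}

#' Read a MAF multiple-alignment file
#'
#' Parses the standard MAF format ("a" block lines followed by "s" sequence
#' lines, \code{s src start size strand srcSize text}). Species are taken as
#' the part of \code{src} before the first dot; the chromosome as the part
#' after it. Only blocks containing the reference species are kept.
#'
#' @param file Path to a MAF file.
#' @param ref_species Reference species identifier (e.g. \code{"mm9"}).
#' @return A list of \code{alignment_block}s, sorted by reference start.
#' @seealso \code{\link{concat_blocks}}
#' @export
read_maf <- function(file, ref_species) {
  lines <- readLines(file)
  lines <- lines[!grepl("^#", lines)]
  blocks <- list()
  cur <- NULL
  flush <- function(cur, blocks) {
    if (is.null(cur) || nrow(cur) == 0L) return(blocks)
    sp <- sub("\\..*$", "", cur$src)
    if (!ref_species %in% sp) return(blocks)
    i <- match(ref_species, sp)
    rows <- cur$text
    names(rows) <- sp
    blk <- alignment_block(rows, ref_species = ref_species,
                           ref_chrom = sub("^[^.]*\\.?", "", cur$src[i]),
                           ref_start = cur$start[i],
                           ref_strand = cur$strand[i])
    c(blocks, list(blk))
  }
  for (ln in lines) {
    if (grepl("^a( |$)", ln)) {
      blocks <- flush(cur, blocks)
      cur <- data.frame(src = character(), start = integer(),
                        strand = character(), text = character())
    } else if (grepl("^s ", ln) && !is.null(cur)) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) < 7L) stop("malformed MAF 's' line: ", ln)
      cur <- rbind(cur, data.frame(src = f[2], start = as.integer(f[3]),
                                   strand = f[5], text = f[7]))
    }
  }
  blocks <- flush(cur, blocks)
  if (length(blocks) == 0L)
    stop("no MAF blocks containing reference species '", ref_species, "'")
  blocks[order(vapply(blocks, function(b) b$ref_start, integer(1)))]
}

#' Concatenate alignment blocks covering one locus
#'
#' Blocks are joined in reference order. Reference bases falling between
#' non-contiguous blocks are not present in the file, so those stretches are
#' filled with \code{N} in the reference row and \code{-} in every other row:
#' no motif can be called there and no species conserves anything there.
#'
#' @param blocks List of \code{alignment_block}s sharing reference species
#'   and chromosome.
#' @return A single \code{alignment_block}.
#' @export
concat_blocks <- function(blocks) {
  stopifnot(length(blocks) >= 1L)
  if (length(blocks) == 1L) return(blocks[[1]])
  ref <- blocks[[1]]$ref_species
  chrom <- blocks[[1]]$ref_chrom
  for (b in blocks)
    if (b$ref_species != ref || b$ref_chrom != chrom)
      stop("blocks must share reference species and chromosome")
  blocks <- blocks[order(vapply(blocks, function(b) b$ref_start, integer(1)))]
  species <- unique(unlist(lapply(blocks, function(b) names(b$rows))))
  out <- stats::setNames(rep("", length(species)), species)
  pos <- blocks[[1]]$ref_start
  for (b in blocks) {
    if (b$ref_start < pos)
      stop("overlapping blocks at reference position ", b$ref_start)
    gap <- b$ref_start - pos
    if (gap > 0L) {
      out[ref] <- paste0(out[ref], strrep("N", gap))
      for (sp in setdiff(species, ref))
        out[sp] <- paste0(out[sp], strrep("-", gap))
    }
    ncol_b <- nchar(b$rows[[1]])
    for (sp in species) {
      seg <- if (sp %in% names(b$rows)) b$rows[[sp]] else strrep("-", ncol_b)
      out[sp] <- paste0(out[sp], seg)
    }
    pos <- b$ref_start + nchar(ref_sequence(b))
  }
  alignment_block(out, ref_species = ref, ref_chrom = chrom,
                  ref_start = blocks[[1]]$ref_start,
                  ref_strand = blocks[[1]]$ref_strand)
}
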