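#' Read a UCSC chrom.sizes file
#'
#' @param path Two-column tab-separated text: chromosome name, length in bp.
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 2L))
    stop("chrom.sizes: expected two tab-separated columns")
  nm <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(len) || any(len != floor(len)))
    stop("chrom.sizes: non-integer length")
  if (any(len <= 0)) stop("chrom.sizes: lengths must be > 0")
  if (anyDuplicated(nm)) stop("chrom.sizes: duplicate chromosome name")
  stats::setNames(as.integer(len), nm)
}

#' @rdname readChromSizes
#' @param sizes Named vector of chromosome lengths.
#' @export
writeChromSizes <- function(sizes, path) {
  writeLines(paste(names(sizes), as.integer(sizes), sep = "\t"), path)
  invisible(path)
}

.apply_seqinfo <- function(gr, chromSizes) {
  if (!is.null(chromSizes)) {
    bad <- setdiff(unique(as.character(seqnames(gr))), names(chromSizes))
    if (length(bad))
      stop("chromosome(s) not in chrom sizes: ", paste(bad, collapse = ", "))
    seqlevels(gr) <- names(chromSizes)
    seqlengths(gr) <- chromSizes
  }
  gr
}

#' Read and write BED intervals
#'
#' BED coordinates are 0-based half-open on disk and converted to the 1-based
#' closed convention of [GenomicRanges::GRanges] on read (and back on write).
#' `readBed()` accepts BED3-BED6; strand `"."` maps to `"*"`.
#' `writeBed()` writes BED6 when any of name/score/strand carries information,
#' BED3 otherwise, sorted by chromosome (lexicographic) then start.
#'
#' @param path File path.
#' @param chromSizes Optional named vector of chromosome lengths; when given,
#'   chromosome names are validated against it and recorded as seqlengths.
#' @return `readBed()`: a `GRanges` (with `name`/`score` metadata columns when
#'   present in the file). `writeBed()`: the path, invisibly.
#' @export
readBed <- function(path, chromSizes = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    gr <- GRanges()
    return(.apply_seqinfo(gr, chromSizes))
  }
  parts <- strsplit(lines, "\t")
  nfield <- lengths(parts)
  if (any(nfield < 3L))
    stop("BED parse error at line ", lineno[which(nfield < 3L)[1]],
         ": fewer than 3 fields")
  chrom <- vapply(parts, `[[`, "", 1L)
  s0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(s0) | is.na(e0))
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1]], ": non-numeric coordinate")
  bad <- which(s0 >= e0 | s0 < 0)
  if (length(bad))
    stop("BED validation error at line ", lineno[bad[1]],
         ": need 0 <= start < end")
  gr <- GRanges(chrom, IRanges(s0 + 1, e0))
  if (min(nfield) >= 4L) mcols(gr)$name <- vapply(parts, `[[`, "", 4L)
  if (min(nfield) >= 5L) {
    sc <- vapply(parts, `[[`, "", 5L)
    mcols(gr)$score <- ifelse(sc == ".", NA_real_,
                              suppressWarnings(as.numeric(sc)))
  }
  if (min(nfield) >= 6L) {
    st <- vapply(parts, `[[`, "", 6L)
    if (any(!st %in% c("+", "-", ".")))
      stop("BED validation error: strand must be one of + - .")
    strand(gr) <- ifelse(st == ".", "*", st)
  }
  .apply_seqinfo(gr, chromSizes)
}

#' @rdname readBed
#' @param gr A `GRanges` of intervals.
#' @export
writeBed <- function(gr, path) {
  gr <- gr[order(as.character(seqnames(gr)), start(gr))]
  if (length(gr) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  hasName <- !is.null(mcols(gr)$name)
  hasScore <- !is.null(mcols(gr)$score)
  hasStrand <- any(as.character(strand(gr)) != "*")
  if (hasName || hasScore || hasStrand) {
    score <- if (hasScore) mcols(gr)$score else 0
    score <- ifelse(is.na(score), ".", format(score, trim = TRUE,
                                              scientific = FALSE))
    lines <- paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   if (hasName) mcols(gr)$name else ".", score,
                   sub("\\*", ".", as.character(strand(gr))), sep = "\t")
  } else {
    lines <- paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write bedGraph coverage tracks
#'
#' Tracks are stored as an [IRanges::RleList] with one run-length-encoded
#' numeric vector per chromosome, covering the full chromosome length.
#' Positions not present in the file take the value `fill` (0 by default;
#' use `fill = NA` to keep unreported regions distinguishable, e.g. for
#' replication-timing ratio tracks). Overlapping records are an error.
#'
#' @param path File path.
#' @param chromSizes Named vector of chromosome lengths. Optional on read (the
#'   last covered position is then taken as the chromosome end).
#' @param fill Value for unreported positions.
#' @param allowNegative Permit negative values (needed for ratio tracks such as
#'   replication timing; plain coverage must be non-negative).
#' @return `readBedGraph()`: an `RleList`. `writeBedGraph()`: the path,
#'   invisibly.
#' @export
readBedGraph <- function(path, chromSizes = NULL, fill = 0,
                         allowNegative = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    if (is.null(chromSizes)) return(methods::as(list(), "RleList"))
    return(methods::as(lapply(chromSizes, function(L) Rle(fill, L)), "RleList"))
  }
  parts <- strsplit(lines, "[\t ]+")
  if (any(lengths(parts) < 4L))
    stop("bedGraph parse error at line ",
         lineno[which(lengths(parts) < 4L)[1]], ": fewer than 4 fields")
  chrom <- vapply(parts, `[[`, "", 1L)
  s0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L)))
  if (anyNA(s0) || anyNA(e0) || anyNA(val))
    stop("bedGraph parse error: non-numeric field")
  if (any(s0 >= e0 | s0 < 0)) stop("bedGraph: need 0 <= start < end")
  if (!all(is.finite(val))) stop("bedGraph: values must be finite")
  if (!allowNegative && any(val < 0))
    stop("bedGraph validation error: negative value (set allowNegative=TRUE ",
         "for ratio tracks)")
  if (!is.null(chromSizes)) {
    bad <- setdiff(unique(chrom), names(chromSizes))
    if (length(bad))
      stop("bedGraph chromosome(s) not in chrom sizes: ",
           paste(bad, collapse = ", "))
    if (any(e0 > chromSizes[chrom]))
      stop("bedGraph record extends past chromosome end")
    chromUniverse <- names(chromSizes)
  } else chromUniverse <- sort(unique(chrom))
  out <- lapply(chromUniverse, function(ch) {
    idx <- which(chrom == ch)
    L <- if (!is.null(chromSizes)) chromSizes[[ch]] else max(e0[idx])
    if (length(idx) == 0L) return(Rle(fill, L))
    o <- idx[order(s0[idx])]
    s <- s0[o]; e <- e0[o]; v <- val[o]
    if (any(s[-1] < e[-length(e)]))
      stop("bedGraph: overlapping records on ", ch)
    # interleave fill-gap runs with record runs
    gapLen <- c(s, L) - c(0, e)
    if (any(gapLen < 0)) stop("bedGraph record extends past chromosome end")
    values <- as.vector(rbind(fill, c(v, fill)))
    lens <- as.vector(rbind(gapLen, c(e - s, 0)))
    Rle(values[lens > 0], lens[lens > 0])
  })
  names(out) <- chromUniverse
  methods::as(out, "RleList")
}

#' @rdname readBedGraph
#' @param track An `RleList` coverage track.
#' @param keepZero Write runs equal to zero as explicit records (needed when a
#'   written zero must be distinguishable from an unreported region).
#' @export
writeBedGraph <- function(track, path, keepZero = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track)) {
    r <- track[[ch]]
    v <- runValue(r)
    ends <- cumsum(runLength(r))
    starts <- ends - runLength(r)   # 0-based
    keep <- !is.na(v) & (keepZero | v != 0)
    if (!any(keep)) next
    writeLines(paste(ch, format(starts[keep], trim = TRUE, scientific = FALSE),
                     format(ends[keep], trim = TRUE, scientific = FALSE),
                     format(v[keep], trim = TRUE, scientific = FALSE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a genome FASTA
#'
#' Wraps [Biostrings::readDNAStringSet], uppercases the sequences, restricts
#' the alphabet to A/C/G/T/N and optionally validates sequence lengths against
#' a chrom.sizes mapping.
#'
#' @param path FASTA file.
#' @param chromSizes Optional named vector of chromosome lengths to validate
#'   against.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
readGenomeFasta <- function(path, chromSizes = NULL) {
  seqs <- readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- DNAStringSet(toupper(as.character(seqs)))
  freq <- letterFrequency(seqs, c("A", "C", "G", "T", "N"))
  widths <- stats::setNames(Biostrings::width(seqs), names(seqs))
  if (any(rowSums(freq) != widths))
    stop("FASTA contains characters outside A/C/G/T/N")
  if (!is.null(chromSizes)) {
    common <- intersect(names(seqs), names(chromSizes))
    if (length(common) == 0L) stop("no FASTA sequence matches chrom sizes")
    bad <- common[widths[common] != chromSizes[common]]
    if (length(bad))
      stop("FASTA length mismatch vs chrom sizes: ", paste(bad, collapse = ", "))
  }
  seqs
}

#' Read gene models from a GTF file
#'
#' Imports `gene` and `exon` features (Ensembl dialect, `gene_id` attribute)
#' via `rtracklayer::import()` and assembles a [GeneModels-class] object. GTF
#' coordinates are 1-based closed; imported ranges keep that convention, which
#' is also the package-internal one. Book-ended or overlapping exons of a gene
#' are merged. Genes lacking an explicit `gene` feature get a span from the
#' union of their exons.
#'
#' @param path GTF file.
#' @param chromSizes Optional named chromosome lengths for validation.
#' @return A [GeneModels-class] object.
#' @export
readGtfGenes <- function(path, chromSizes = NULL) {
  gtf <- rtracklayer::import(path, format = "gtf")
  if (is.null(mcols(gtf)$gene_id)) stop("GTF lacks gene_id attributes")
  type <- as.character(mcols(gtf)$type)
  geneRows <- gtf[type == "gene"]
  exonRows <- gtf[type == "exon"]
  ids <- unique(mcols(c(geneRows, exonRows))$gene_id)
  exonsBy <- split(exonRows, factor(mcols(exonRows)$gene_id, levels = ids))
  spans <- lapply(ids, function(id) {
    g <- geneRows[mcols(geneRows)$gene_id == id]
    if (length(g) == 1L) return(g)
    ex <- exonsBy[[id]]
    if (length(ex) == 0L) stop("gene ", id, " has neither gene nor exon rows")
    r <- range(ex)
    mcols(r)$gene_id <- id
    r
  })
  genes <- do.call(c, lapply(spans, function(g) {
    GRanges(seqnames(g), ranges(g), strand = strand(g),
            gene_id = mcols(g)$gene_id)
  }))
  if (any(as.character(strand(genes)) == "*"))
    stop("GTF gene without strand")
  exons <- GRangesList(lapply(seq_along(ids), function(i) {
    ex <- exonsBy[[ids[i]]]
    g <- genes[i]
    if (length(ex) == 0L) { mcols(g) <- NULL; strand(g) <- "*"; return(reduce(g)) }
    if (min(start(ex)) < start(g) || max(end(ex)) > end(g))
      stop("validation error: exon outside gene span for ", ids[i])
    reduce(ex, ignore.strand = TRUE)
  }))
  names(exons) <- ids
  genes <- .apply_seqinfo(genes, chromSizes)
  GeneModels(genes, exons)
}

#' Write gene models as GTF
#'
#' Emits one `gene` row and one `exon` row per exon, 1-based closed
#' coordinates, Ensembl-style `gene_id`/`transcript_id` attributes.
#'
#' @param gm A [GeneModels-class] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeGtfGenes <- function(gm, path) {
  g <- geneRanges(gm)
  ids <- geneIds(gm)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(g)) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', ids[i], ids[i])
    writeLines(paste(as.character(seqnames(g)[i]), "rloopscape", "gene",
                     start(g)[i], end(g)[i], ".", as.character(strand(g)[i]),
                     ".", attrs, sep = "\t"), con)
    ex <- geneExons(gm)[[ids[i]]]
    for (j in seq_along(ex))
      writeLines(paste(as.character(seqnames(ex)[j]), "rloopscape", "exon",
                       start(ex)[j], end(ex)[j], ".",
                       as.character(strand(g)[i]), ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' @param path GMT file: tab-separated `term`, `description`, then member
#'   genes, one set per line.
#' @return `readGmt()`: a named list of character vectors of gene ids, with a
#'   `description` attribute per element.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 3L))
    stop("GMT: each line needs term, description and >= 1 gene")
  sets <- lapply(parts, function(p) {
    g <- unique(p[-(1:2)])
    attr(g, "description") <- p[2]
    g
  })
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("GMT: duplicate term name")
  sets
}

#' @rdname readGmt
#' @param sets Named list of character vectors.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    d <- attr(sets[[nm]], "description")
    paste(c(nm, if (is.null(d)) nm else d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
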