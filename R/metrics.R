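#' Size expansion/contraction between orthologous segments
#'
#' @param species Species label.
#' @param segment_kb Size of the sequenced segment (kb).
#' @param corresponding_kb Size of the corresponding region in the
#'   reference species (kb).
#' @return One-row data frame: `species`, `segment_kb`,
#'   `corresponding_kb`, `delta_kb` (signed, `segment - corresponding`,
#'   carried at input precision), `direction`
#'   (`expansion`/`contraction`/`equal`).
#' @export
size_delta <- function(species, segment_kb, corresponding_kb) {
  if (segment_kb <= 0 || corresponding_kb <= 0)
    stop("sizes must be positive")
  delta <- segment_kb - corresponding_kb
  data.frame(species = species, segment_kb = segment_kb,
             corresponding_kb = corresponding_kb, delta_kb = delta,
             direction = if (delta > 0) "expansion"
             else if (delta < 0) "contraction" else "equal",
             stringsAsFactors = FALSE)
}

#' Per-class sequence composition of a region
#'
#' Per-class occupied bp is the union length of that class's annotations
#' (within-class overlaps merged and counted once); fractions are
#' relative to the region length.
#'
#' @param x An annotated [region()].
#' @param classes Annotation classes to summarize (default: all present).
#' @return Data frame: `class`, `bp`, `fraction`.
#' @export
composition_fractions <- function(x, classes = NULL) {
  stopifnot(inherits(x, "region"))
  n <- region_length(x)
  if (nrow(x$ann) > 0L && (any(x$ann$start < 1L) || any(x$ann$end > n)))
    stop("annotation exceeds region bounds")
  if (is.null(classes)) classes <- unique(x$ann$class)
  rows <- lapply(classes, function(cl) {
    a <- x$ann[x$ann$class == cl, , drop = FALSE]
    bp <- if (nrow(a) == 0L) 0L else
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = a$start, end = a$end))))
    data.frame(class = cl, bp = bp, fraction = bp / n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(class = character(), bp = integer(),
                                      fraction = numeric(),
                                      stringsAsFactors = FALSE)
  out
}

#' Size-variation report across species
#'
#' Assembles [size_delta()] rows into the standard size-variation table:
#' one row per species with separate contraction and expansion columns
#' (kb at integer precision in the serialized table; full precision is
#' retained in the returned data frame).
#'
#' @param entries Data frame of [size_delta()] rows (rbind-ed), in the
#'   desired order.
#' @return Data frame: `species`, `segment_kb`, `corresponding_kb`,
#'   `contraction_kb`, `expansion_kb` (empty, `NA`, where not
#'   applicable).
#' @export
table1_report <- function(entries) {
  stopifnot(nrow(entries) >= 1L)
  data.frame(species = entries$species,
             segment_kb = entries$segment_kb,
             corresponding_kb = entries$corresponding_kb,
             contraction_kb = ifelse(entries$delta_kb < 0,
                                     -entries$delta_kb, NA_real_),
             expansion_kb = ifelse(entries$delta_kb > 0,
                                   entries$delta_kb, NA_real_),
             stringsAsFactors = FALSE)
}

#' Write / read the size-variation report as TSV
#'
#' Empty optional cells are serialized as empty strings (not 0) and read
#' back as `NA`, so the report round-trips.
#'
#' @param report Data frame from [table1_report()].
#' @param path File path.
#' @return `read_size_report` returns the data frame.
#' @export
write_size_report <- function(report, path) {
  out <- report
  for (col in c("contraction_kb", "expansion_kb"))
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         format(out[[col]], trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_size_report
#' @export
read_size_report <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", rep("numeric", 4L)))
  df
}

# -- shared format layer -----------------------------------------------------

#' Write a region's sequence as FASTA
#' @param x A [region()].
#' @param path Output path.
#' @export
write_region_fasta <- function(x, path) {
  s <- Biostrings::DNAStringSet(x$seq)
  names(s) <- x$name
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Read a FASTA file into a list of unannotated regions
#' @param path FASTA path.
#' @export
read_region_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(s), function(i)
    region(as.character(s[[i]]), name = names(s)[i]))
}

#' Write region annotations as GFF3 (1-based inclusive)
#' @param x A [region()].
#' @param path Output path.
#' @export
write_region_gff3 <- function(x, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for GFF3 output")
  a <- x$ann
  gr <- GenomicRanges::GRanges(
    seqnames = x$name,
    ranges = IRanges::IRanges(start = a$start, end = a$end),
    strand = a$strand)
  gr$type <- a$class
  gr$ID <- a$id
  gr$state <- a$state
  gr$Parent <- a$parent
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation file into an annotation data frame
#' @param path GFF3 path.
#' @export
read_region_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for GFF3 input")
  gr <- rtracklayer::import(path, format = "gff3")
  parent <- if (!is.null(gr$Parent)) {
    vapply(as.list(gr$Parent), function(p)
      if (length(p)) as.character(p[[1L]]) else NA_character_,
      character(1))
  } else NA_character_
  normalize_annotations(data.frame(
    id = as.character(gr$ID), class = as.character(gr$type),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    state = if (is.null(gr$state)) NA_character_ else gr$state,
    parent = parent, stringsAsFactors = FALSE))
}

#' Write / read a marker matrix as TSV (1/0/NA)
#'
#' First column `variety`, optional second column `group`, then one
#' column per marker.
#'
#' @param m Marker matrix with optional `groups` attribute.
#' @param path File path.
#' @export
write_marker_matrix <- function(m, path) {
  groups <- attr(m, "groups")
  df <- data.frame(variety = rownames(m), stringsAsFactors = FALSE)
  if (!is.null(groups)) df$group <- groups[rownames(m)]
  df <- cbind(df, as.data.frame(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_marker_matrix
#' @export
read_marker_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  has_group <- "group" %in% colnames(df)
  first_marker <- if (has_group) 3L else 2L
  m <- as.matrix(df[, first_marker:ncol(df), drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- df$variety
  if (has_group)
    attr(m, "groups") <- stats::setNames(df$group, df$variety)
  m
}

#' Write a truth log as JSON
#' @param log A `truth_log`.
#' @param path Output path.
#' @export
write_truth_log <- function(log, path) {
  jsonlite::write_json(unclass(log), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
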