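#' Genomic region container
#'
#' A `region` bundles a nucleotide sequence with its feature annotations
#' (genes and transposable elements). Coordinates are 1-based inclusive
#' throughout the package, so annotations serialize to GFF3 without
#' conversion.
#'
#' @param seq Character scalar, the nucleotide sequence (A/C/G/T).
#' @param ann Annotation data frame, see [empty_annotations()] for the
#'   column contract. Missing columns are filled with `NA`.
#' @param name Region identifier (used as the GFF3/FASTA sequence name).
#' @return An object of class `region`: a list with elements `name`, `seq`
#'   and `ann`.
#' @export
region <- function(seq, ann = empty_annotations(), name = "region") {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  ann <- normalize_annotations(ann)
  if (nrow(ann) > 0L) {
    if (any(ann$start < 1L) || any(ann$end > nchar(seq)))
      stop("annotation exceeds region bounds")
    if (any(ann$end < ann$start))
      stop("annotation with end < start")
  }
  structure(list(name = name, seq = toupper(seq), ann = ann),
            class = "region")
}

#' Empty annotation table
#'
#' Column contract for region annotations:
#' `id` feature identifier; `class` one of `gene`, `LTR_retro`,
#' `DNA_transposon`, `Helitron`, `other`; `start`,`end` 1-based inclusive;
#' `strand` `+`/`-`; `ltr_length` LTR length in bp (LTR elements only);
#' `full_length` expected intact element length; `state` structural state
#' (`intact`, `solo`, `truncated`, `split`); `tsd` target-site duplication
#' sequence; `parent` parent element id for split fragments.
#'
#' @return Zero-row data frame with the annotation columns.
#' @export
empty_annotations <- function() {
  data.frame(id = character(), class = character(),
             start = integer(), end = integer(), strand = character(),
             ltr_length = integer(), full_length = integer(),
             state = character(), tsd = character(), parent = character(),
             stringsAsFactors = FALSE)
}

ann_columns <- c("id", "class", "start", "end", "strand",
                 "ltr_length", "full_length", "state", "tsd", "parent")

normalize_annotations <- function(ann) {
  stopifnot(is.data.frame(ann))
  for (col in ann_columns) {
    if (is.null(ann[[col]])) {
      ann[[col]] <- if (col %in% c("start", "end", "ltr_length", "full_length"))
        NA_integer_ else NA_character_
    }
  }
  ann <- ann[, ann_columns, drop = FALSE]
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  rownames(ann) <- NULL
  ann
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %s: %s bp, %d annotations\n", x$name,
              format(nchar(x$seq), big.mark = ","), nrow(x$ann)))
  if (nrow(x$ann) > 0L)
    print(table(x$ann$class))
  invisible(x)
}

#' Region length in bp
#' @param x A `region`.
#' @export
region_length <- function(x) nchar(x$seq)

#' Subset annotations by feature class
#' @param x A `region`.
#' @param classes Character vector of classes to keep.
#' @return Annotation data frame rows of the requested classes.
#' @export
annotations_of_class <- function(x, classes) {
  x$ann[x$ann$class %in% classes, , drop = FALSE]
}

#' TE annotations of a region
#' @param x A `region`.
#' @export
te_annotations <- function(x) {
  annotations_of_class(x, c("LTR_retro", "DNA_transposon", "Helitron"))
}

#' Gene annotations of a region
#' @param x A `region`.
#' @export
gene_annotations <- function(x) annotations_of_class(x, "gene")

# -- small sequence utilities ------------------------------------------------

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
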