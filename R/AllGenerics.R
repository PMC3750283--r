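#' @rdname TranscriptSet-accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("transcriptNames", function(x) standardGeneric("transcriptNames"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("toxinClass", function(x) standardGeneric("toxinClass"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("cdsSeqs", function(x) standardGeneric("cdsSeqs"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("isToxin", function(x) standardGeneric("isToxin"))

#' Accessors for TranscriptSet
#'
#' `transcriptIds()` and `transcriptNames()` return the stable ids and the
#' class-cluster-letter labels; `toxinClass()` the class label per transcript;
#' `cdsRanges()` the CDS windows as an [IRanges::IRanges] (1-based, as is
#' conventional for ranges); `cdsSeqs()` the extracted coding sequences;
#' `isToxin()` a logical marking venom components.
#'
#' @param x A `TranscriptSet`.
#' @return See details per accessor.
#' @name TranscriptSet-accessors
NULL

#' @rdname TranscriptSet-accessors
setMethod("transcriptIds", "TranscriptSet", function(x) as.character(x@anno$id))

#' @rdname TranscriptSet-accessors
setMethod("transcriptNames", "TranscriptSet",
          function(x) as.character(x@anno$name))

#' @rdname TranscriptSet-accessors
setMethod("toxinClass", "TranscriptSet",
          function(x) as.character(x@anno$toxin_class))

#' @rdname TranscriptSet-accessors
setMethod("cdsRanges", "TranscriptSet", function(x)
  IRanges::IRanges(start = x@anno$cds_start + 1L, end = x@anno$cds_end,
                   names = as.character(x@anno$id)))

#' @rdname TranscriptSet-accessors
setMethod("cdsSeqs", "TranscriptSet", function(x)
  Biostrings::subseq(x@sequences, start = x@anno$cds_start + 1L,
                     end = x@anno$cds_end))

#' @rdname TranscriptSet-accessors
setMethod("isToxin", "TranscriptSet",
          function(x) x@anno$toxin_class != "NONTOXIN")

#' @rdname TranscriptSet-accessors
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@sequences))

#' Subset a TranscriptSet
#'
#' @param x A `TranscriptSet`.
#' @param i index vector (integer, logical, or transcript ids).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@anno$id)
  methods::new("TranscriptSet", sequences = x@sequences[i],
               anno = x@anno[i, , drop = FALSE])
})

#' Sequences of a TranscriptSet
#'
#' @param x A `TranscriptSet`.
#' @return The underlying `DNAStringSet`.
#' @export
setGeneric("transcriptSeqs", function(x) standardGeneric("transcriptSeqs"))

#' @rdname transcriptSeqs
setMethod("transcriptSeqs", "TranscriptSet", function(x) x@sequences)

#' Annotation table of a TranscriptSet
#'
#' @param x A `TranscriptSet`.
#' @return The annotation `DataFrame` (0-based half-open CDS coordinates).
#' @export
setGeneric("transcriptAnno", function(x) standardGeneric("transcriptAnno"))

#' @rdname transcriptAnno
setMethod("transcriptAnno", "TranscriptSet", function(x) x@anno)
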