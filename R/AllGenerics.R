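#' @include AllClasses.R
NULL

#' Accessors for RnaRecordSet
#'
#' @param x an [RnaRecordSet-class].
#' @return `recordIds`, `rnaSequences`, `families`, `clusters` return
#'   character vectors; `basePairs` a list of two-column integer matrices;
#'   `seqLengths` an integer vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))
#' @rdname accessors
#' @export
setGeneric("rnaSequences", function(x) standardGeneric("rnaSequences"))
#' @rdname accessors
#' @export
setGeneric("families", function(x) standardGeneric("families"))
#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname accessors
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))
#' @rdname accessors
#' @export
setGeneric("seqLengths", function(x) standardGeneric("seqLengths"))

#' @rdname accessors
setMethod("recordIds", "RnaRecordSet", function(x) x@id)
#' @rdname accessors
setMethod("rnaSequences", "RnaRecordSet", function(x) {
  stats::setNames(x@sequence, x@id)
})
#' @rdname accessors
setMethod("families", "RnaRecordSet", function(x) stats::setNames(x@family, x@id))
#' @rdname accessors
setMethod("clusters", "RnaRecordSet", function(x) stats::setNames(x@cluster, x@id))
#' @rdname accessors
setMethod("basePairs", "RnaRecordSet", function(x) stats::setNames(x@pairs, x@id))
#' @rdname accessors
setMethod("seqLengths", "RnaRecordSet", function(x) {
  stats::setNames(nchar(x@sequence), x@id)
})

#' @export
setMethod("length", "RnaRecordSet", function(x) length(x@id))

#' Subset an RnaRecordSet by position, logical mask or record id
#' @param x an [RnaRecordSet-class].
#' @param i integer, logical or character index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "RnaRecordSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) {
    idx <- match(i, x@id)
    if (anyNA(idx)) stop("unknown record id(s): ",
                         paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  methods::initialize(x, id = x@id[i], sequence = x@sequence[i],
                      family = x@family[i], cluster = x@cluster[i],
                      pairs = x@pairs[i])
})

#' Concatenate RnaRecordSets
#' @param x,... [RnaRecordSet-class] objects.
#' @export
setMethod("c", "RnaRecordSet", function(x, ...) {
  xs <- c(list(x), list(...))
  methods::new("RnaRecordSet",
    id = unlist(lapply(xs, function(z) z@id)),
    sequence = unlist(lapply(xs, function(z) z@sequence)),
    family = unlist(lapply(xs, function(z) z@family)),
    cluster = unlist(lapply(xs, function(z) z@cluster)),
    pairs = do.call(c, lapply(xs, function(z) z@pairs)))
})

setMethod("show", "RnaRecordSet", function(object) {
  n <- length(object)
  cat(sprintf("RnaRecordSet with %d record%s\n", n, if (n == 1) "" else "s"))
  if (n > 0) {
    L <- nchar(object@sequence)
    cat(sprintf("  lengths: %d-%d nt; %d with structure; families: %s\n",
                min(L), max(L), sum(vapply(object@pairs, nrow, 1L) > 0),
                paste(utils::head(unique(stats::na.omit(object@family)), 5),
                      collapse = ", ")))
  }
  invisible(object)
})

setMethod("show", "SplitSpec", function(object) {
  cat(sprintf("SplitSpec (%s, seed %d): TR %d / VL %d / TS %d\n",
              object@level, object@seed, length(object@tr),
              length(object@vl), length(object@ts)))
  if (!is.na(object@holdoutFamily))
    cat(sprintf("  held-out family: %s\n", object@holdoutFamily))
  invisible(object)
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d members in %d clusters\n",
              length(object@member), length(unique(object@representative))))
  invisible(object)
})

setMethod("show", "SeqFold2DModel", function(object) {
  cfg <- object@config
  cat(sprintf("SeqFold2DModel (N = %d, C = %d, %s): %s parameters\n",
              cfg@N, cfg@C, cfg@blockType,
              format(countParams(cfg), big.mark = ",")))
  if (nrow(object@history) > 0)
    cat(sprintf("  trained %d epochs; best VL F1 = %.3f\n",
                nrow(object@history), max(object@history$vl_f1, na.rm = TRUE)))
  invisible(object)
})

#' @rdname accessors
#' @export
setGeneric("clusterMembership", function(x) standardGeneric("clusterMembership"))
#' @rdname accessors
setMethod("clusterMembership", "ClusterSet", function(x) {
  data.frame(member_id = x@member, representative_id = x@representative,
             stringsAsFactors = FALSE)
})
#' @rdname accessors
#' @export
setGeneric("clusterRepresentatives",
           function(x) standardGeneric("clusterRepresentatives"))
#' @rdname accessors
setMethod("clusterRepresentatives", "ClusterSet",
          function(x) unique(x@representative))
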