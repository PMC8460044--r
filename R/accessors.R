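#' @rdname CircleSet-class
#' @export
setMethod("circleIds", "CircleSet", function(x) as.character(x@info$circle_id))

#' @rdname CircleSet-class
#' @export
setMethod("circleSeqs", "CircleSet", function(x) x@seqs)

#' @rdname CircleSet-class
#' @export
setMethod("circleInfo", "CircleSet", function(x) x@info)

#' @rdname CircleSet-class
#' @export
setMethod("hasHim", "CircleSet", function(x)
  setNames(x@info$has_him, x@info$circle_id))

#' @rdname CircleSet-class
#' @export
setMethod("himTruth", "CircleSet", function(x) x@info[x@info$has_him, ])

#' @rdname CircleSet-class
#' @export
setMethod("length", "CircleSet", function(x) length(x@seqs))

#' @rdname CircleSet-class
#' @param i index (numeric, logical or circle_id character)
#' @param j,drop,... ignored
#' @export
setMethod("[", "CircleSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, circleIds(x))
  initialize(x, seqs = x@seqs[i], info = x@info[i, , drop = FALSE])
})

setMethod("show", "CircleSet", function(object) {
  n <- length(object)
  cat(sprintf("CircleSet with %d circle%s (%d carrying an intact HIM)\n",
              n, if (n == 1L) "" else "s",
              sum(object@info$has_him & object@info$mutation == "none")))
  if (n) {
    w <- width(object@seqs)
    cat(sprintf("  lengths: %d-%d nt; coordinates originate at the WIM\n",
                min(w), max(w)))
  }
})

#' @rdname HostGenome-class
#' @export
setMethod("hostSeqs", "HostGenome", function(x) x@seqs)

#' @rdname HostGenome-class
#' @export
setMethod("hostGenes", "HostGenome", function(x) x@genes)

#' @rdname HostGenome-class
#' @export
setMethod("scaffoldLengths", "HostGenome", function(x)
  setNames(width(x@seqs), names(x@seqs)))

setMethod("show", "HostGenome", function(object) {
  cat(sprintf("HostGenome: %d scaffold(s), %s bp, %d gene(s)\n",
              length(object@seqs),
              format(sum(width(object@seqs)), big.mark = ","),
              length(object@genes)))
})

#' @rdname BreakSiteProfile-class
#' @export
setMethod("nChimeras", "BreakSiteProfile", function(x) x@nChimeras)

#' @rdname BreakSiteProfile-class
#' @export
setMethod("modalPair", "BreakSiteProfile", function(x)
  c(U = x@modalUp, D = x@modalDown))

#' @rdname BreakSiteProfile-class
#' @export
setMethod("conservedFraction", "BreakSiteProfile", function(x)
  x@conservedFraction)

setMethod("show", "BreakSiteProfile", function(object) {
  cat(sprintf(
    "BreakSiteProfile for %s: %d chimeras, modal pair (U=%s, D=%s), conserved %.3f\n",
    object@circleId, object@nChimeras,
    ifelse(is.na(object@modalUp), "-", object@modalUp),
    ifelse(is.na(object@modalDown), "-", object@modalDown),
    object@conservedFraction))
})

setMethod("show", "DeletionCall", function(object) {
  if (object@status == "ok" || object@status == "degenerate")
    cat(sprintf("DeletionCall %s [%s]: %d-%d (%d nt), junctions U=%d D=%d\n",
                object@circleId, object@status, object@delStart,
                object@delEnd, object@delLen, object@upJunction,
                object@downJunction))
  else cat(sprintf("DeletionCall %s: %s\n", object@circleId, object@status))
})

setMethod("show", "HimCall", function(object) {
  cat(sprintf("HimCall %s: intact=%s", object@deletion@circleId,
              object@intact))
  if (length(object@arm8))
    cat(sprintf(", arm8 %s/%s", object@arm8$up_seq, object@arm8$down_seq))
  if (length(object@arm5))
    cat(sprintf(", arm5 %s/%s", object@arm5$up_seq, object@arm5$down_seq))
  if (!is.na(object@proximity))
    cat(sprintf(", WIM-HIM proximity %d nt", object@proximity))
  cat("\n")
})

#' @rdname IntegrationIndexSeries-class
#' @export
setMethod("indexTable", "IntegrationIndexSeries", function(x) x@table)

#' @rdname IntegrationIndexSeries-class
#' @export
setMethod("timingClass", "IntegrationIndexSeries", function(x) x@timingClass)

setMethod("show", "IntegrationIndexSeries", function(object) {
  cat(sprintf("IntegrationIndexSeries %s (%s)\n", object@circleId,
              ifelse(is.na(object@timingClass), "unclassified",
                     object@timingClass)))
  print(object@table, row.names = FALSE)
})
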