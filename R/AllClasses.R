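#' A set of circular viral segments with motif annotation
#'
#' `CircleSet` holds the sequences of circular dsDNA viral segments together
#' with their wasp integration motif (WIM) span and, where present, the
#' ground-truth or called host integration motif (HIM). Coordinates are
#' 1-based inclusive on the circle; position 1 is the first base of the WIM,
#' mirroring the coordinate origin used for the printed motif tables.
#'
#' The per-circle metadata (`circleInfo`) holds columns: `circle_id`,
#' `length`, `wim_end`, `has_him`, `mutation` (`none`, `M1`, `M2`, `M3`),
#' the four arm spans (`arm8_up_start`/`arm8_up_len`, `arm5_up_start`/
#' `arm5_up_len`, and the `_down` pairs), the deletable `spacer_start`/
#' `spacer_end`, and the truth WIM-HIM `proximity`.
#'
#' @slot seqs a [Biostrings::DNAStringSet] of circle sequences.
#' @slot info a [S4Vectors::DataFrame] of per-circle metadata (see above).
#' @export
setClass("CircleSet", representation(seqs = "DNAStringSet", info = "DataFrame"))

.validCircleSet <- function(object) {
  msgs <- character()
  info <- object@info
  need <- c("circle_id", "length", "wim_end", "has_him", "mutation",
            "arm8_up_start", "arm8_up_len", "arm5_up_start", "arm5_up_len",
            "spacer_start", "spacer_end",
            "arm5_down_start", "arm5_down_len", "arm8_down_start",
            "arm8_down_len", "proximity")
  miss <- setdiff(need, colnames(info))
  if (length(miss))
    return(paste("missing info columns:", paste(miss, collapse = ", ")))
  if (length(object@seqs) != nrow(info))
    return("seqs and info disagree in length")
  if (nrow(info) == 0L) return(TRUE)
  if (!identical(names(object@seqs), as.character(info$circle_id)))
    msgs <- c(msgs, "names(seqs) must equal info$circle_id")
  if (!all(width(object@seqs) == info$length))
    msgs <- c(msgs, "sequence widths disagree with info$length")
  ## WIM must contain the tetramer AGCT
  wim <- subseq(object@seqs, 1L, pmin(info$wim_end, width(object@seqs)))
  if (!all(vcountPattern("AGCT", wim) > 0L))
    msgs <- c(msgs, "every WIM must contain the tetramer AGCT")
  ## intact HIMs: arm pairs must be exact reverse complements
  intact <- which(info$has_him & info$mutation == "none")
  for (i in intact) {
    s <- as.character(object@seqs[[i]])
    a8u <- substr(s, info$arm8_up_start[i],
                  info$arm8_up_start[i] + info$arm8_up_len[i] - 1L)
    a8d <- substr(s, info$arm8_down_start[i],
                  info$arm8_down_start[i] + info$arm8_down_len[i] - 1L)
    a5u <- substr(s, info$arm5_up_start[i],
                  info$arm5_up_start[i] + info$arm5_up_len[i] - 1L)
    a5d <- substr(s, info$arm5_down_start[i],
                  info$arm5_down_start[i] + info$arm5_down_len[i] - 1L)
    if (!identical(revcompChr(a8u), a8d) || !identical(revcompChr(a5u), a5d))
      msgs <- c(msgs, sprintf("circle %s: HIM arms are not reverse complements",
                              info$circle_id[i]))
    hi <- c(info$arm8_up_start[i], info$arm8_down_start[i] +
              info$arm8_down_len[i] - 1L, info$spacer_start[i],
            info$spacer_end[i])
    if (any(hi < 1L) || any(hi > info$length[i]))
      msgs <- c(msgs, sprintf("circle %s: annotation out of bounds",
                              info$circle_id[i]))
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("CircleSet", .validCircleSet)

#' A (simulated) host genome with gene annotation
#'
#' Scaffold sequences plus gene intervals (1-based inclusive, GFF3-style).
#'
#' @slot seqs a [Biostrings::DNAStringSet] of scaffolds.
#' @slot genes a [GenomicRanges::GRanges] of gene spans with seqlengths set.
#' @export
setClass("HostGenome", representation(seqs = "DNAStringSet", genes = "GRanges"))

.validHostGenome <- function(object) {
  msgs <- character()
  sl <- setNames(width(object@seqs), names(object@seqs))
  g <- object@genes
  if (length(g)) {
    bad <- !(as.character(seqnames(g)) %in% names(sl))
    if (any(bad))
      msgs <- c(msgs, paste("gene scaffolds absent from assembly:",
                            paste(unique(as.character(seqnames(g))[bad]),
                                  collapse = ", ")))
    ok <- !bad
    oob <- ok & (start(g) < 1L | end(g) > sl[as.character(seqnames(g))])
    if (any(oob))
      msgs <- c(msgs, sprintf("gene intervals out of scaffold bounds: %s",
                              paste(sprintf("%s:%d-%d",
                                            as.character(seqnames(g))[oob],
                                            start(g)[oob], end(g)[oob]),
                                    collapse = ", ")))
    if (any(start(g) > end(g)))
      msgs <- c(msgs, "malformed gene intervals (start > end)")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("HostGenome", .validHostGenome)

#' Per-circle tally of viral-side junction positions
#'
#' Junctions are split by side: "up" junctions are circle positions where the
#' retained viral arc ends (coordinates increase toward the junction), "down"
#' junctions where it begins. A conservative (HIM-mediated) break produces one
#' dominant cluster on each side; the two modal clusters jointly define the
#' conserved break site.
#'
#' @slot circleId circle identifier.
#' @slot upCounts,downCounts named integer vectors, names are circle positions.
#' @slot nChimeras total chimeric reads tallied.
#' @slot modalUp,modalDown modal junction positions (NA when a side is empty).
#' @slot conservedCount chimeras falling in either modal cluster.
#' @slot conservedFraction conservedCount / nChimeras (0 for empty profiles).
#' @slot clusterTol clustering tolerance in nt.
#' @slot circleLength circle length (NA if unknown; disables wrap clustering).
#' @export
setClass("BreakSiteProfile",
         representation(circleId = "character", upCounts = "integer",
                        downCounts = "integer", nChimeras = "integer",
                        modalUp = "integer", modalDown = "integer",
                        conservedCount = "integer",
                        conservedFraction = "numeric", clusterTol = "integer",
                        circleLength = "integer"))

setValidity("BreakSiteProfile", function(object) {
  msgs <- character()
  if (sum(object@upCounts) + sum(object@downCounts) != object@nChimeras)
    msgs <- c(msgs, "junction counts do not sum to nChimeras")
  if (object@conservedCount > object@nChimeras)
    msgs <- c(msgs, "conservedCount exceeds nChimeras")
  if (length(msgs)) msgs else TRUE
})

#' A called deletion between the modal junction pair of a circle
#'
#' The removed stretch is `delStart..delEnd` (1-based inclusive, circular);
#' `upJunction` is the last retained base before it and `downJunction` the
#' first retained base after it. `status` is one of `"ok"`, `"degenerate"`
#' (zero-length deletion) or `"not_applicable"` (no modal pair, i.e. a
#' random-broken circle).
#'
#' @export
setClass("DeletionCall",
         representation(circleId = "character", status = "character",
                        delStart = "integer", delEnd = "integer",
                        delLen = "integer", upJunction = "integer",
                        downJunction = "integer", circleLength = "integer"))

setValidity("DeletionCall", function(object) {
  if (object@status != "ok") return(TRUE)
  L <- object@circleLength
  if (object@delLen < 1L) return("delLen must be >= 1 when status is 'ok'")
  if (circGapLen(object@upJunction, object@downJunction, L) != object@delLen)
    return("delLen inconsistent with junction pair under circular arithmetic")
  TRUE
})

#' A detected host integration motif (HIM)
#'
#' Wraps a [DeletionCall] with the detected inverted-repeat arm pairs. Each
#' arm slot is a list with `up_seq`, `down_seq`, `up_start`, `up_end`,
#' `down_start`, `down_end`, `len` (empty list when not found). `intact` is
#' TRUE only when both pairs were found with exact reverse complementarity.
#' `degraded` lists near-miss pairs (one mismatch allowed) for arms that were
#' not found exactly. `proximity` is the WIM-HIM distance in nt (NA until
#' computed).
#'
#' @export
setClass("HimCall",
         representation(deletion = "DeletionCall", arm8 = "list",
                        arm5 = "list", intact = "logical", degraded = "list",
                        proximity = "integer"))

#' Integration-index time course for one circle
#'
#' @slot circleId circle identifier.
#' @slot table data.frame with columns `timepoint_h`, `mean_index_pct`,
#'   `sd_index_pct`, `n_replicates`, `below_baseline`.
#' @slot timingClass one of `"EIC"`, `"MIC"`, `"LIC"`, `"unclassified"`, or
#'   NA when not yet classified.
#' @export
setClass("IntegrationIndexSeries",
         representation(circleId = "character", table = "data.frame",
                        timingClass = "character"))
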