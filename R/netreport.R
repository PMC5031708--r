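# Directed-network assembly and export.
#
# Significant edges per ANOVA effect are collected into a GCNetwork,
# classified by anatomical area pair, and (for the age and interaction
# effects) by developmental trend: per-condition least-squares slopes of
# edge weight on age, a slope being called "up"/"down" only when its
# two-sided p < 0.05, else "flat".

# slope direction of y on age: "up", "down" or "flat"
.slopeCall <- function(y, age, alpha = 0.05) {
  N <- length(age)
  xc <- age - mean(age)
  Sxx <- sum(xc^2)
  b <- sum(xc * y) / Sxx
  rss <- sum((y - mean(y) - b * xc)^2)
  se <- sqrt(rss / (N - 2) / Sxx)
  p <- if (se == 0) as.numeric(b != 0) * 0 else
    2 * pt(abs(b / se), N - 2, lower.tail = FALSE)
  if (p < alpha) (if (b > 0) "up" else "down") else "flat"
}

#' Classify the developmental trend subtype of an interaction edge
#'
#' For an edge with a significant age-by-condition interaction, fits
#' per-condition least-squares slopes of edge weight on age and assigns
#' one of four subtypes. The sign of the NORE-age correlation selects
#' the positive or negative family; within a family the own-condition
#' (positive) or other-condition (negative) slope must be "up" while
#' the opposite condition is "flat" or "down". Edges matching no
#' pattern (e.g. both slopes flat) are reported as unclassified
#' (\code{NA}) rather than forced into a subtype.
#'
#' @param yOwn,yOther per-participant edge weights under each condition.
#' @param age participant ages in years.
#' @param alpha two-sided level for calling a slope non-flat
#'   (default 0.05).
#' @return one of \code{"pos_own_up_other_flat"},
#'   \code{"pos_own_up_other_down"}, \code{"neg_other_up_own_flat"},
#'   \code{"neg_other_up_own_down"}, or \code{NA_character_}.
#' @export
classifyTrend <- function(yOwn, yOther, age, alpha = 0.05) {
  if (length(yOwn) != length(age) || length(yOther) != length(age))
    stop("yOwn, yOther and age must have equal length")
  if (sd(yOwn - yOther) == 0) return(NA_character_)  # no interaction possible
  own <- .slopeCall(yOwn, age, alpha)
  oth <- .slopeCall(yOther, age, alpha)
  noreSlope <- sum((age - mean(age)) * (yOwn - yOther))
  if (noreSlope > 0) {
    if (own == "up" && oth == "flat") return("pos_own_up_other_flat")
    if (own == "up" && oth == "down") return("pos_own_up_other_down")
  } else {
    if (oth == "up" && own == "flat") return("neg_other_up_own_flat")
    if (oth == "up" && own == "down") return("neg_other_up_own_down")
  }
  NA_character_
}

#' Assemble the significant-edge network for one effect
#'
#' Collects the edges whose \code{sig_<effect>} flag is set in an edge
#' statistics table, labels each with its anatomical
#' \code{\link{classifyEdge}} class, and annotates the developmental
#' trend: for the age effect, the direction of the condition-mean
#' weight's slope on age; for the interaction effect, the
#' \code{\link{classifyTrend}} subtype; for the race effect, which
#' condition is stronger (sign of the mean NORE).
#'
#' @param stats edge statistics table from
#'   \code{\link{cohortEdgeStats}}.
#' @param effect \code{"age"}, \code{"race"} or \code{"interaction"}.
#' @param own,other optional stacked weight arrays (channel x channel x
#'   participant); required for trend annotation.
#' @param age participant ages aligned with the arrays.
#' @param nChannels montage size (default 46).
#' @return a \linkS4class{GCNetwork}; empty networks are allowed.
#' @export
assembleNetwork <- function(stats, effect = c("age", "race", "interaction"),
                            own = NULL, other = NULL, age = NULL,
                            nChannels = 46L) {
  effect <- match.arg(effect)
  sigCol <- paste0("sig_", effect)
  if (!sigCol %in% names(stats))
    stop("stats lacks column ", sigCol)
  sel <- stats[which(stats[[sigCol]]), , drop = FALSE]
  sel <- sel[order(sel$from, sel$to), , drop = FALSE]
  trend <- rep(NA_character_, nrow(sel))
  if (nrow(sel) && !is.null(own) && !is.null(other) && !is.null(age)) {
    for (k in seq_len(nrow(sel))) {
      yOwn <- own[sel$from[k], sel$to[k], ]
      yOther <- other[sel$from[k], sel$to[k], ]
      trend[k] <- switch(effect,
        age = .slopeCall((yOwn + yOther) / 2, age),
        interaction = classifyTrend(yOwn, yOther, age),
        race = if (mean(yOwn - yOther) > 0) "own_stronger" else "other_stronger")
    }
  }
  edges <- if (nrow(sel)) {
    # the anatomical block rule only applies to the full montage
    cls <- if (nChannels == 46L) classifyEdge(sel$from, sel$to)
           else NA_character_
    data.frame(from = sel$from, to = sel$to, edgeClass = cls,
               trend = trend,
               sel[, setdiff(names(sel), c("from", "to", "edgeClass")),
                   drop = FALSE],
               row.names = NULL)
  } else {
    data.frame(from = integer(), to = integer(),
               edgeClass = character(), trend = character())
  }
  new("GCNetwork", effect = effect, edges = edges,
      nChannels = as.integer(nChannels))
}

#' Export a network as GraphML and a TSV edge list
#'
#' Writes a GraphML file whose 46 nodes carry the montage metadata (MNI
#' coordinates, Brodmann area, AAL label, region, hemisphere) and whose
#' directed edges carry the class and trend attributes, plus a flat TSV
#' edge list next to it. Output is deterministic: edges are ordered by
#' (from, to).
#'
#' @param network a \linkS4class{GCNetwork}.
#' @param path output GraphML path; the TSV replaces the extension with
#'   \code{.tsv}.
#' @param registry channel registry data.frame (default packaged
#'   montage) providing node attributes.
#' @return named character vector of the two written paths, invisibly.
#' @seealso \code{\link{readGraphEdges}}
#' @export
exportGraph <- function(network, path, registry = channelRegistry()) {
  edges <- networkEdges(network)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  nodes <- data.frame(name = as.character(registry$id),
                      x = registry$x, y = registry$y, z = registry$z,
                      ba = registry$ba, aal = registry$aal,
                      region = registry$region,
                      hemisphere = registry$hemisphere)
  ecols <- intersect(c("from", "to", "edgeClass", "trend",
                       "boot_age", "boot_race", "boot_interaction",
                       "nore_r"), names(edges))
  d <- edges[, ecols, drop = FALSE]
  d$from <- as.character(d$from)
  d$to <- as.character(d$to)
  d$trend <- as.character(d$trend)
  d$trend[is.na(d$trend)] <- "unclassified"
  g <- igraph::graph_from_data_frame(d, directed = TRUE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  tsvPath <- sub("\\.[^.]*$", ".tsv", path)
  if (identical(tsvPath, path)) tsvPath <- paste0(path, ".tsv")
  write.table(edges, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(graphml = path, tsv = tsvPath))
}

#' Read back the edge list of an exported GraphML network
#'
#' @param path a GraphML file written by \code{\link{exportGraph}}.
#' @return data.frame of directed edges with their attributes; node ids
#'   are restored as integers.
#' @export
readGraphEdges <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  d <- igraph::as_data_frame(g, what = "edges")
  d$from <- as.integer(d$from)
  d$to <- as.integer(d$to)
  d[order(d$from, d$to), , drop = FALSE]
}

#' Per-effect summary of a network
#'
#' Counts of significant edges by anatomical class and trend.
#'
#' @param network a \linkS4class{GCNetwork}.
#' @return data.frame with columns \code{effect}, \code{edgeClass},
#'   \code{trend}, \code{n}.
#' @export
networkSummary <- function(network) {
  edges <- networkEdges(network)
  if (!nrow(edges))
    return(data.frame(effect = character(), edgeClass = character(),
                      trend = character(), n = integer()))
  tr <- ifelse(is.na(edges$trend), "unclassified", edges$trend)
  agg <- aggregate(list(n = seq_len(nrow(edges))),
                   by = list(edgeClass = edges$edgeClass, trend = tr),
                   FUN = length)
  data.frame(effect = networkEffect(network), agg[order(agg$edgeClass), ],
             row.names = NULL)
}
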