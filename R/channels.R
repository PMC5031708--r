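# Channel registry: montage metadata and anatomical edge classification.
#
# The 46-channel montage has two probe sets: channels 1-24 cover the
# frontal cortex (lowest probes along Fp1-Fp2) and channels 25-46 cover
# the occipital cortex (lowest probes along O1-O2). Region membership is
# defined by this id block, not by parsing AAL labels (some frontal-set
# labels, e.g. PreCG, are not frontal-lobe gyri).

.N_CHANNELS <- 46L
.N_FRONTAL  <- 24L

#' Edge class labels
#'
#' The four anatomical classes of a directed channel pair: within the
#' frontal block (channels 1-24), within the occipital block (25-46), or
#' between blocks in either direction.
#'
#' @return character vector of the four class labels.
#' @export
edgeClassLevels <- function() {
  c("intra_frontal", "intra_occipital",
    "inter_frontal_to_occipital", "inter_occipital_to_frontal")
}

#' Load a channel registry table
#'
#' Reads a tab-separated montage table (columns \code{id}, \code{x},
#' \code{y}, \code{z}, \code{ba}, \code{aal}) and validates it: ids must
#' cover exactly 1..46 with no duplicates, coordinates must be numeric,
#' and the hemisphere derived from the AAL label prefix is cross-checked
#' against the sign of the MNI x coordinate (mismatches warn, they are
#' not errors, to tolerate midline channels).
#'
#' @param path path to a TSV file; defaults to the packaged montage
#'   registry (MNI coordinates, Brodmann areas and AAL labels of the
#'   46-channel frontal + occipital probe arrangement).
#' @return data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{z}, \code{ba}, \code{aal}, \code{region} (\code{"frontal"} or
#'   \code{"occipital"}) and \code{hemisphere} (\code{"L"}/\code{"R"}).
#' @examples
#' reg <- loadChannelTable()
#' reg[reg$id == 1, ]   # L IFGtriang at MNI (-54, 36, 3), BA 45
#' @seealso \code{\link{classifyEdge}}, \code{\link{writeChannelTable}}
#' @export
loadChannelTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "channels_mni_aal.tsv",
                        package = "fnirsGCA", mustWork = TRUE)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "x", "y", "z", "ba", "aal")
  if (!all(need %in% names(tab)))
    stop("channel registry must carry columns: ", paste(need, collapse = ", "))
  num <- suppressWarnings(lapply(tab[c("id", "x", "y", "z", "ba")], as.numeric))
  if (anyNA(num$x) || anyNA(num$y) || anyNA(num$z))
    stop("malformed coordinate in channel registry (non-numeric x/y/z)")
  if (anyNA(num$id) || anyNA(num$ba))
    stop("malformed id or Brodmann area in channel registry")
  ids <- as.integer(num$id)
  if (anyDuplicated(ids))
    stop("duplicate channel id in registry")
  if (!identical(sort(ids), seq_len(.N_CHANNELS)))
    stop("channel registry must cover ids 1..", .N_CHANNELS,
         " exactly (got ", length(ids), " rows)")
  reg <- data.frame(
    id  = ids,
    x   = num$x, y = num$y, z = num$z,
    ba  = as.integer(num$ba),
    aal = trimws(tab$aal),
    stringsAsFactors = FALSE
  )
  reg <- reg[order(reg$id), , drop = FALSE]
  rownames(reg) <- NULL
  reg$region <- ifelse(reg$id <= .N_FRONTAL, "frontal", "occipital")
  hemi <- substr(reg$aal, 1L, 1L)
  if (!all(hemi %in% c("L", "R")))
    stop("AAL labels must start with an L/R hemisphere prefix")
  reg$hemisphere <- hemi
  mismatch <- (hemi == "L" & reg$x >= 0) | (hemi == "R" & reg$x < 0)
  if (any(mismatch))
    warning("hemisphere label disagrees with MNI x sign for channel(s): ",
            paste(reg$id[mismatch], collapse = ", "))
  reg
}

#' @rdname loadChannelTable
#' @export
channelRegistry <- loadChannelTable

#' Write a channel registry table
#'
#' Writes the six authoritative columns as TSV so that
#' \code{loadChannelTable(writeChannelTable(reg, f))} is an identity.
#'
#' @param registry data.frame as returned by \code{\link{loadChannelTable}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeChannelTable <- function(registry, path) {
  write.table(registry[, c("id", "x", "y", "z", "ba", "aal")],
              file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify a directed channel pair by cortical area
#'
#' Maps an ordered channel pair to one of the four anatomical edge
#' classes using the probe-block rule: channels 1-24 are frontal,
#' 25-46 occipital. Vectorized over \code{from}/\code{to}.
#'
#' @param from,to integer channel ids in 1..46; \code{from != to}.
#' @return character vector of \code{\link{edgeClassLevels}} values.
#' @examples
#' classifyEdge(2, 18)    # intra_frontal
#' classifyEdge(25, 19)   # inter_occipital_to_frontal
#' classifyEdge(40, 43)   # intra_occipital
#' @export
classifyEdge <- function(from, to) {
  from <- as.integer(from); to <- as.integer(to)
  if (length(from) != length(to))
    stop("from and to must have equal length")
  bad <- from < 1L | from > .N_CHANNELS | to < 1L | to > .N_CHANNELS |
    is.na(from) | is.na(to)
  if (any(bad))
    stop("channel id out of range 1..", .N_CHANNELS)
  if (any(from == to))
    stop("self-loops are undefined: from and to must differ")
  fFront <- from <= .N_FRONTAL
  tFront <- to <= .N_FRONTAL
  out <- character(length(from))
  out[fFront & tFront]   <- "intra_frontal"
  out[!fFront & !tFront] <- "intra_occipital"
  out[fFront & !tFront]  <- "inter_frontal_to_occipital"
  out[!fFront & tFront]  <- "inter_occipital_to_frontal"
  out
}

# All 46*45 ordered channel pairs, ordered by (from, to).
.allEdges <- function(nChannels = .N_CHANNELS) {
  grid <- expand.grid(to = seq_len(nChannels), from = seq_len(nChannels))
  grid <- grid[grid$from != grid$to, c("from", "to")]
  grid <- grid[order(grid$from, grid$to), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}
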