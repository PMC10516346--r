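#' Competitive network container
#'
#' A complete directed graph over the assayed species at one pH. Edge width
#' encodes competitive superiority under one of four metrics; node size is
#' the sum of a species' outgoing edge widths.
#'
#' @param metric one of "single_control", "svs_control", "eoc_wins", "ioa".
#' @param ph pH level the network describes.
#' @param edges data.frame: from, to, width (>= 0).
#' @return list of class `competitive_network`: metric, ph, nodes
#'   (data.frame id, size), edges.
#' @export
competitive_network <- function(metric, ph, edges) {
  stopifnot(metric %in% c("single_control", "svs_control", "eoc_wins",
                          "ioa"))
  edges$width <- as.numeric(edges$width)  # strip tapply's 1-D array dims
  if (any(edges$width < 0)) stop("edge widths must be >= 0", call. = FALSE)
  ids <- sort(unique(c(edges$from, edges$to)))
  out_sum <- vapply(ids, function(s) sum(edges$width[edges$from == s]),
                    numeric(1))
  structure(list(
    metric = metric, ph = ph,
    nodes = data.frame(id = ids, size = unname(out_sum),
                       stringsAsFactors = FALSE),
    edges = edges[order(edges$from, edges$to), , drop = FALSE]
  ), class = "competitive_network")
}

#' Control-growth network
#'
#' Edge width from i to j is species i's mean control growth rate divided by
#' species j's — how much faster i would colonise than its hypothetical
#' opponent. Built from single-plug or SvS control fits at one pH.
#'
#' @param fits growth-fit rows (one plug per plate for SvS).
#' @param ph pH level.
#' @param which "single" or "svs" control plates.
#' @param response "growth_rate" or "colony_size".
#' @return a [competitive_network()].
#' @export
build_control_network <- function(fits, ph,
                                  which = c("single", "svs"),
                                  response = c("growth_rate",
                                               "colony_size")) {
  which <- match.arg(which)
  response <- match.arg(response)
  col <- if (response == "growth_rate") "rate" else "max_area"
  treat <- if (which == "single") "single" else "SvS"
  sub <- fits[fits$treatment == treat & fits$ph == ph, , drop = FALSE]
  means <- tapply(sub[[col]], sub$focal, mean)
  if (any(is.na(means)) || any(means <= 0)) {
    stop("domain error: nonpositive or missing mean control response",
         call. = FALSE)
  }
  ids <- sort(names(means))
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  pairs$width <- means[pairs$from] / means[pairs$to]
  metric <- if (which == "single") "single_control" else "svs_control"
  competitive_network(metric, ph, pairs)
}

#' EoC-wins network
#'
#' Each competition plate pits the two plugs' EoC values head to head. Edge
#' width from i to j is the percentage of usable plates of the (i, j)
#' pairing on which i's EoC exceeded j's, with exact ties counting half a
#' win to each side — so opposing widths always sum to 100.
#'
#' @param eoc_records output of [compute_eoc()] (both plugs per plate).
#' @param ph pH level.
#' @return a [competitive_network()]. Pairings with no usable plate are
#'   omitted with a warning.
#' @export
build_eoc_network <- function(eoc_records, ph) {
  sub <- eoc_records[eoc_records$ph == ph, , drop = FALSE]
  ids <- sort(unique(c(sub$focal, sub$opponent)))
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      a <- ids[i]; b <- ids[j]
      pa <- sub[sub$focal == a & sub$opponent == b, ]
      pb <- sub[sub$focal == b & sub$opponent == a, ]
      common <- intersect(pa$plate_id, pb$plate_id)
      if (!length(common)) {
        warning("no usable plates for pairing ", a, " vs ", b, " at pH ",
                ph, "; edge omitted", call. = FALSE)
        next
      }
      ea <- pa$eoc[match(common, pa$plate_id)]
      eb <- pb$eoc[match(common, pb$plate_id)]
      wins_a <- sum(ea > eb) + 0.5 * sum(ea == eb)
      w_a <- 100 * wins_a / length(common)
      rows[[length(rows) + 1L]] <- data.frame(
        from = c(a, b), to = c(b, a), width = c(w_a, 100 - w_a),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no usable pairings at pH ", ph, call. = FALSE)
  competitive_network("eoc_wins", ph, do.call(rbind, rows))
}

#' Antagonism-score network
#'
#' Edge width from i to j is species i's mean index-of-antagonism score over
#' scored plates against j.
#'
#' @param ioa_records output of [score_ioa()].
#' @param ph pH level.
#' @return a [competitive_network()]. Unscored pairings are omitted with a
#'   warning.
#' @export
build_ioa_network <- function(ioa_records, ph) {
  sub <- ioa_records[ioa_records$ph == ph, , drop = FALSE]
  # each scored plate gives both directions: focal and opponent scores
  both <- rbind(
    data.frame(from = sub$focal, to = sub$opponent, score = sub$focal_score,
               stringsAsFactors = FALSE),
    data.frame(from = sub$opponent, to = sub$focal,
               score = sub$opponent_score, stringsAsFactors = FALSE)
  )
  ids <- sort(unique(c(both$from, both$to)))
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  key <- paste(both$from, both$to)
  means <- tapply(both$score, key, mean)
  pairs$width <- means[paste(pairs$from, pairs$to)]
  if (anyNA(pairs$width)) {
    miss <- pairs[is.na(pairs$width), ]
    warning("unscored pairing(s) omitted: ",
            paste(paste(miss$from, miss$to, sep = "->"), collapse = ", "),
            call. = FALSE)
    pairs <- pairs[!is.na(pairs$width), , drop = FALSE]
  }
  competitive_network("ioa", ph, pairs)
}

#' Export a competitive network to JSON and edge-list CSV
#'
#' Writes a lossless JSON description `{metric, ph, nodes:[{id,size}],
#' edges:[{from,to,width}]}` and, if `csv_path` is given, a from/to/width
#' edge list.
#'
#' @param network a [competitive_network()].
#' @param path JSON output file.
#' @param csv_path optional edge-list CSV output file.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, csv_path = NULL) {
  obj <- list(metric = network$metric, ph = network$ph,
              nodes = network$nodes, edges = network$edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(csv_path)) {
    utils::write.csv(network$edges, csv_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a network written by [export_network()]
#'
#' @param path JSON file.
#' @return a [competitive_network()] rebuilt from the edge list; node sizes
#'   are recomputed from outgoing widths (and must match the stored sizes).
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- competitive_network(obj$metric, obj$ph, obj$edges)
  stored <- obj$nodes[order(obj$nodes$id), ]
  if (!isTRUE(all.equal(unname(net$nodes$size), unname(stored$size),
                        tolerance = 1e-9))) {
    stop("stored node sizes disagree with recomputed out-width sums",
         call. = FALSE)
  }
  net
}
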