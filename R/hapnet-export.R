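#' Convert a haplotype network to an igraph graph
#'
#' Vertex attributes: \code{freq} (sample count; 0 for inferred medians),
#' \code{inferred}, and \code{pops} (population composition as
#' \code{pop:count} pairs separated by \code{;}).  Edge attributes:
#' \code{weight} plus per-class mutation counts \code{ts} and \code{tv}.
#'
#' @param net an \code{mp_network}.
#' @return an \code{igraph} object.
#' @export
as_igraph <- function(net) {
  comp <- vapply(seq_len(nrow(net$nodes)), function(i) {
    id <- net$nodes$id[i]
    if (!net$nodes$observed[i] || !id %in% rownames(net$counts)) return("")
    cnt <- net$counts[id, ]
    cnt <- cnt[cnt > 0]
    paste(paste0(names(cnt), ":", cnt), collapse = ";")
  }, character(1))
  # inferred as 0/1: logical attributes do not survive every export format
  vertices <- data.frame(name = net$nodes$id, freq = net$nodes$freq,
                         inferred = as.integer(!net$nodes$observed),
                         pops = comp, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = vertices)
}

#' Export a haplotype network to GraphML, DOT and an edge list
#'
#' @param net an \code{mp_network}.
#' @param path output path; extension selects the format (\code{.graphml},
#'   \code{.dot}/\code{.gv}, or \code{.tsv} for an edge list).
#' @return the path, invisibly.
#' @export
export_network <- function(net, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  ext <- tolower(sub(".*\\.", "", path))
  g <- as_igraph(net)
  if (ext == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (ext %in% c("dot", "gv")) {
    igraph::write_graph(g, path, format = "dot")
  } else if (ext == "tsv") {
    write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("unsupported extension: ", ext)
  invisible(path)
}
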