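# Machine-readable reports: stable JSON (schema "capnet-1") and TSV.

fit_to_list <- function(fit) {
  list(fitted = fit$fitted,
       exponent_b = fit$exponent_b,
       prefactor_a = fit$prefactor_a,
       pearson_r = fit$pearson_r,
       r_squared = fit$r_squared,
       n_points = fit$n_points)
}

topology_to_list <- function(x) {
  list(n_nodes = x$n_nodes,
       n_edges_simple = x$n_edges_simple,
       n_interactions_raw = x$n_interactions_raw,
       avg_clustering = x$avg_clustering,
       diameter = x$diameter,
       avg_neighbors = x$avg_neighbors,
       char_path_length = x$char_path_length,
       degree_fit = fit_to_list(x$degree_fit),
       clustering_fit = fit_to_list(x$clustering_fit))
}

#' Serialize a report to JSON
#'
#' Stable, byte-reproducible JSON for the package's report objects
#' ([topology_report()], [knockout_report()], [find_bridging_nodes()]
#' output): fixed key order, no locale-dependent number formatting, `null`
#' for undefined statistics, and a schema version field (`"capnet-1"`).
#' Two serializations of the same object are byte-identical.
#'
#' @param x A `topology_report`, `knockout_result`, or the bridge-report
#'   data frame returned by [find_bridging_nodes()].
#' @param path Optional file to write; when `NULL` the JSON text is
#'   returned.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_json <- function(x, path = NULL) {
  body <- if (inherits(x, "topology_report")) {
    c(list(schema = "capnet-1", type = "topology_report"),
      topology_to_list(x))
  } else if (inherits(x, "knockout_result")) {
    list(schema = "capnet-1", type = "knockout_result",
         removed = as.list(x$removed),
         orphans = as.list(sort_c(x$orphans)),
         edges_lost = x$edges_lost,
         pre = topology_to_list(x$pre),
         post = topology_to_list(x$post))
  } else if (is.data.frame(x) && all(c("node", "is_bridge") %in% names(x))) {
    list(schema = "capnet-1", type = "bridge_report",
         nodes = lapply(seq_len(nrow(x)), function(i) {
           list(node = x$node[[i]],
                own_compartment = x$own_compartment[[i]],
                covered = as.list(x$covered[[i]]),
                is_bridge = x$is_bridge[[i]])
         }))
  } else {
    stop("report_json: unsupported object of class ",
         paste(class(x), collapse = "/"))
  }
  txt <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA,
                          null = "null", na = "null", pretty = TRUE)
  txt <- paste0(as.character(txt), "\n")
  if (!is.null(path)) {
    writeChar(txt, path, eos = NULL)
    return(invisible(txt))
  }
  txt
}

# deterministic TSV writer (no quoting surprises, no row names)
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

bridge_report_tsv <- function(bridges, path) {
  out <- data.frame(
    node = bridges$node,
    own_compartment = bridges$own_compartment,
    covered = vapply(bridges$covered, paste, "", collapse = ","),
    is_bridge = bridges$is_bridge,
    stringsAsFactors = FALSE)
  write_tsv_plain(out, path)
}
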