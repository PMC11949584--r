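#' Read a time-series panel from delimited text
#'
#' Each file holds one session: a header row of node labels and one row per
#' time point (TSV by default; `.csv` files are comma-separated). Multiple
#' files are stacked as separate sessions. Columns of later files are
#' realigned to the label order of the first file; a permuted header is
#' accepted with a warning, a mismatched label set is an error.
#'
#' Alternatively, a single file may carry a `session` column whose runs of
#' equal values delimit contiguous sessions.
#'
#' @param paths Character vector of file paths, one per session.
#' @param tr_seconds Sampling interval of the recordings.
#' @param sep Field separator; default inferred from the first file's
#'   extension (`","` for `.csv`, tab otherwise).
#' @return A [ts_panel()] with session boundaries set per file.
#' @export
read_panel <- function(paths, tr_seconds = 1, sep = NULL) {
  stopifnot(length(paths) >= 1L)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", paths[1L], ignore.case = TRUE)) "," else "\t"
  }
  read_one <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            colClasses = "character",
                            check.names = FALSE, comment.char = "")
    session_id <- NULL
    if ("session" %in% names(df)) {
      session_id <- df[["session"]]
      df <- df[, names(df) != "session", drop = FALSE]
    }
    mat <- matrix(NA_real_, nrow(df), ncol(df),
                  dimnames = list(NULL, names(df)))
    for (col in seq_len(ncol(df))) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]))
      if (length(bad)) {
        stop("non-numeric cell in ", path, " at data row ", bad[1L],
             ", column '", names(df)[col], "': '", df[[col]][bad[1L]], "'")
      }
      if (anyNA(v)) {
        stop("missing value in ", path, " at data row ",
             which(is.na(v))[1L], ", column '", names(df)[col], "'")
      }
      mat[, col] <- v
    }
    attr(mat, "session_lengths") <- if (is.null(session_id)) nrow(mat) else {
      as.integer(rle(session_id)$lengths)
    }
    mat
  }
  mats <- lapply(paths, read_one)
  labels <- colnames(mats[[1L]])
  for (k in seq_along(mats)[-1L]) {
    lk <- colnames(mats[[k]])
    if (!identical(lk, labels)) {
      if (!setequal(lk, labels)) {
        stop("header mismatch: ", paths[k], " has labels {",
             paste(setdiff(lk, labels), collapse = ", "),
             "} not present in ", paths[1L])
      }
      warning("columns of ", paths[k], " permuted relative to ",
              paths[1L], "; realigned by label")
      sl <- attr(mats[[k]], "session_lengths")
      mats[[k]] <- mats[[k]][, labels, drop = FALSE]
      attr(mats[[k]], "session_lengths") <- sl
    }
  }
  ts_panel(do.call(rbind, mats), node_labels = labels,
           tr_seconds = tr_seconds,
           session_lengths = unlist(lapply(mats, attr, "session_lengths")))
}

#' Write a panel to delimited text
#'
#' One file per session, suffixed `_session<k>` when the panel has several.
#'
#' @param panel A [ts_panel()].
#' @param path Output path (the first/only session's file).
#' @param sep Field separator; default tab.
#' @return Invisibly, the vector of files written.
#' @export
write_panel <- function(panel, path, sep = "\t") {
  stopifnot(inherits(panel, "ts_panel"))
  rows <- session_rows(panel)
  files <- if (length(rows) == 1L) path else {
    stem <- sub("(\\.[^.]*)$", "", path)
    ext <- sub(paste0("^", gsub("([.\\\\])", "\\\\\\1", stem)), "", path)
    paste0(stem, "_session", seq_along(rows), ext)
  }
  for (k in seq_along(rows)) {
    utils::write.table(panel$values[rows[[k]], , drop = FALSE], files[k],
                       sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(files)
}

#' Write and read summary graphs
#'
#' A summary graph is written as two companion text files: a CSV edge list
#' (`source_label, target_label, strength_pval, lags` with the
#' contributing lags semicolon-joined) carrying `tau_max` and
#' `alpha_level` as `#`-comment header lines, and a dense 0/1 adjacency
#' CSV whose first column and header carry the node labels.
#' `read_graph(edge_list, adjacency)` inverts the pair exactly
#' (adjacency, strengths and lag provenance round-trip).
#'
#' @param graph A `summary_graph`.
#' @param edge_list_path,adjacency_path Paths of the two files.
#' @return `write_graph`: invisibly, the two paths. `read_graph`: a
#'   `summary_graph`.
#' @export
write_graph <- function(graph, edge_list_path, adjacency_path) {
  stopifnot(inherits(graph, "summary_graph"))
  con <- file(edge_list_path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# tau_max: ", graph$tau_max),
               paste0("# alpha_level: ",
                      format(graph$alpha_level, digits = 17))), con)
  idx <- which(graph$adjacency == 1L, arr.ind = TRUE)
  lags <- character(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    lags[r] <- paste(which(graph$lag_provenance[idx[r, 1L], idx[r, 2L], ]) - 1L,
                     collapse = ";")
  }
  df <- data.frame(
    source_label = graph$node_labels[idx[, 1L]],
    target_label = graph$node_labels[idx[, 2L]],
    strength_pval = format(graph$strength[idx], digits = 17),
    lags = lags, stringsAsFactors = FALSE
  )
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)

  adj <- graph$adjacency
  adj_df <- data.frame(node = graph$node_labels, adj, check.names = FALSE,
                       stringsAsFactors = FALSE)
  colnames(adj_df) <- c("node", graph$node_labels)
  utils::write.table(adj_df, adjacency_path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(c(edge_list_path, adjacency_path))
}

#' @rdname write_graph
#' @export
read_graph <- function(edge_list_path, adjacency_path) {
  header <- readLines(edge_list_path, n = 2L)
  if (!all(grepl("^# ", header))) {
    stop("malformed edge list: expected '# tau_max:' and '# alpha_level:' ",
         "header lines")
  }
  tau_max <- as.integer(sub("^# tau_max: *", "", header[1L]))
  alpha_level <- as.numeric(sub("^# alpha_level: *", "", header[2L]))
  edges <- utils::read.csv(edge_list_path, comment.char = "#",
                           colClasses = c("character", "character",
                                          "numeric", "character"))
  adj_df <- utils::read.csv(adjacency_path, check.names = FALSE,
                            colClasses = "character")
  labels <- adj_df[[1L]]
  if (!identical(labels, colnames(adj_df)[-1L])) {
    stop("adjacency CSV row labels do not match its column labels")
  }
  N <- length(labels)
  adjacency <- matrix(as.integer(as.matrix(adj_df[, -1L, drop = FALSE])),
                      N, N, dimnames = list(labels, labels))
  strength <- matrix(1, N, N, dimnames = list(labels, labels))
  prov <- array(FALSE, c(N, N, tau_max + 1L),
                dimnames = list(labels, labels, paste0("lag", 0:tau_max)))
  if (nrow(edges)) {
    si <- match(edges$source_label, labels)
    ti <- match(edges$target_label, labels)
    if (anyNA(si) || anyNA(ti)) {
      bad <- unique(c(edges$source_label[is.na(si)],
                      edges$target_label[is.na(ti)]))
      stop("edge list refers to unknown node label(s): ",
           paste(bad, collapse = ", "))
    }
    for (r in seq_len(nrow(edges))) {
      strength[si[r], ti[r]] <- edges$strength_pval[r]
      for (l in as.integer(strsplit(edges$lags[r], ";")[[1L]])) {
        prov[si[r], ti[r], l + 1L] <- TRUE
      }
    }
  }
  structure(
    list(adjacency = adjacency, strength = strength, lag_provenance = prov,
         node_labels = labels, alpha_level = alpha_level, tau_max = tau_max),
    class = "summary_graph"
  )
}

#' Write an edge tensor as a long-format CSV
#'
#' @param tensor An `edge_tensor`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_edge_tensor <- function(tensor, path) {
  utils::write.csv(edge_tensor_table(tensor), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write a plain adjacency matrix CSV
#'
#' The dense labelled dialect of [write_graph()]: header = node labels,
#' first column = node labels. Used for ground-truth matrices and for
#' `evaluate` inputs.
#'
#' @param x Square matrix with labels (row/col names) for writing.
#' @param path CSV path.
#' @return `read_adjacency`: a labelled numeric matrix.
#' @export
write_adjacency <- function(x, path) {
  x <- as.matrix(x)
  labels <- rownames(x)
  if (is.null(labels)) labels <- paste0("n", seq_len(nrow(x)))
  df <- data.frame(node = labels, x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("node", labels)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  labels <- df[[1L]]
  if (!identical(labels, colnames(df)[-1L])) {
    stop("adjacency CSV row labels do not match its column labels")
  }
  matrix(as.numeric(as.matrix(df[, -1L, drop = FALSE])),
         length(labels), length(labels), dimnames = list(labels, labels))
}

#' Read a node-partition table
#'
#' CSV with columns `node_label`, `subnetwork` and optionally `hemisphere`.
#'
#' @param path CSV path.
#' @return A [node_partition()].
#' @export
read_partition <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("node_label", "subnetwork")
  if (!all(need %in% names(df))) {
    stop("partition table must have columns node_label, subnetwork")
  }
  node_partition(df$node_label, df$subnetwork,
                 if ("hemisphere" %in% names(df)) df$hemisphere else NULL)
}
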