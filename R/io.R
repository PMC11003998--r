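# Readers and writers: delimited sequence data and the JSON network
# container {nodes, cardinalities, b0_encoding, btrans_encoding, cpts?}.

.sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a discrete sequence dataset from delimited text
#'
#' Expects a header `sequence_id, time, <node names...>` with integer-coded
#' states; comma or tab delimited.  Rows are sorted on load; time indices
#' must be contiguous from 0 within each sequence.
#'
#' @param path File path.
#' @param cardinalities Optional per-node state counts.
#' @return A `seq_dataset`.
#' @export
read_sequence_data <- function(path, cardinalities = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = .sniff_delim(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sequence_id", "time")
  if (!all(need %in% names(df))) {
    stop("dataset must have sequence_id and time columns", call. = FALSE)
  }
  node_cols <- setdiff(names(df), need)
  for (cl in c("time", node_cols)) {
    v <- df[[cl]]
    if (!is.numeric(v) || any(v != floor(v))) {
      stop("column ", cl, " must be integer-coded", call. = FALSE)
    }
    df[[cl]] <- as.integer(v)
  }
  seq_dataset(df, cardinalities = cardinalities)
}

#' Write a sequence dataset as delimited text
#'
#' @param dataset A `seq_dataset`.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_sequence_data <- function(dataset, path, sep = ",") {
  utils::write.table(dataset$data, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.cpts_to_json <- function(cpts) {
  ser <- function(seg) {
    lapply(seg, function(cpt) {
      list(parents = as.integer(cpt$parents),
           table = unname(apply(cpt$table, 1L, function(rw) as.numeric(rw),
                                simplify = FALSE)))
    })
  }
  list(b0 = ser(cpts$b0), btrans = ser(cpts$btrans))
}

.cpts_from_json <- function(obj) {
  de <- function(seg) {
    lapply(seg, function(cpt) {
      tab <- do.call(rbind, lapply(cpt$table, as.numeric))
      .validate_cpt_table(tab)
      list(parents = as.integer(unlist(cpt$parents)), table = tab)
    })
  }
  list(b0 = de(obj$b0), btrans = de(obj$btrans))
}

#' Write a 2T-BN to the JSON network container
#'
#' Serializes node names, cardinalities, the bitstring encodings of both
#' graphs and (when present) the CPTs.
#'
#' @param bn A `two_slice_bn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(bn, path) {
  obj <- list(nodes = bn$b0$nodes,
              cardinalities = as.integer(bn$cardinalities),
              b0_encoding = encode_graph(bn$b0),
              btrans_encoding = encode_graph(bn$btrans))
  if (!is.null(bn$cpts)) obj$cpts <- .cpts_to_json(bn$cpts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a 2T-BN from the JSON network container
#'
#' Validity (acyclicity, no bidirectional pairs, temporal rule) is enforced
#' on load; malformed containers raise errors.
#'
#' @param path File path.
#' @return A `two_slice_bn`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("nodes", "cardinalities", "b0_encoding", "btrans_encoding")
  if (!all(need %in% names(obj))) {
    stop("network container missing fields: ",
         paste(setdiff(need, names(obj)), collapse = ", "), call. = FALSE)
  }
  nodes <- as.character(unlist(obj$nodes))
  n <- length(nodes)
  b0 <- decode_graph(obj$b0_encoding, n, nodes = nodes)
  bt <- decode_graph(obj$btrans_encoding, 2L * n,
                     nodes = c(paste0(nodes, "_t"), paste0(nodes, "_t1")),
                     require_dag = FALSE)
  bn <- two_slice_bn(b0, bt,
                     cardinalities = as.integer(unlist(obj$cardinalities)))
  if (!is.null(obj$cpts)) bn$cpts <- .cpts_from_json(obj$cpts)
  bn
}
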