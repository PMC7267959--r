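#' Write / read a labelled connectivity matrix as delimited text
#'
#' Tab-separated matrix with channel labels as header row and first
#' column. `read_matrix` checks symmetry to 1e-9 and restores the band
#' tag from a comment line.
#'
#' @param m A `wnet_conn`.
#' @param path File path.
#' @return `write_matrix`: the path, invisibly. `read_matrix`: a `wnet_conn`.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "wnet_conn"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#band: ", m$band), con)
  writeLines(paste0("#n_epochs: ", m$n_epochs_used), con)
  writeLines(paste(c("label", m$labels), collapse = "\t"), con)
  for (i in seq_len(nrow(m$wpli))) {
    writeLines(paste(c(m$labels[i], sprintf("%.17g", m$wpli[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @param path File path.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  band <- sub("^#band: ", "", grep("^#band:", meta, value = TRUE))
  n_epochs <- suppressWarnings(as.integer(
    sub("^#n_epochs: ", "", grep("^#n_epochs:", meta, value = TRUE))))
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1], "\t")[[1]][-1]
  rows <- strsplit(body[-1], "\t")
  labels <- vapply(rows, `[`, "", 1)
  mat <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  dimnames(mat) <- list(labels, header)
  if (!identical(labels, header)) stop_invalid("matrix row/column labels differ")
  if (max(abs(mat - t(mat))) > 1e-9) {
    stop_invalid("matrix in ", path, " is asymmetric beyond tolerance 1e-9")
  }
  connectivity_matrix((mat + t(mat)) / 2, band = if (length(band)) band else "band",
                      labels = labels,
                      n_epochs = if (length(n_epochs)) n_epochs else NA_integer_)
}

#' Write / read a sensor layout as whitespace-delimited text
#'
#' Columns: label, x, y, z (mm) and region.
#'
#' @param layout A `wnet_layout`.
#' @param path File path.
#' @export
write_layout <- function(layout, path) {
  assert_layout(layout)
  write.table(layout, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!"region" %in% names(df)) df$region <- "central"
  assert_layout(df)
  class(df) <- c("wnet_layout", "data.frame")
  df
}

#' Write / read an epoched recording in the native text container
#'
#' Plain-text format: comment header (`#subject`, `#fs`, `#channels`,
#' `#dims`) followed by one line of samples per (epoch, channel), in
#' epoch-major order, at full double precision. Round trips are exact.
#'
#' @param recording A `wnet_recording`.
#' @param path File path.
#' @export
write_epochs <- function(recording, path) {
  stopifnot(inherits(recording, "wnet_recording"))
  d <- dim(recording$epochs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#subject: ", recording$subject_id),
               paste0("#fs: ", sprintf("%.17g", recording$fs)),
               paste0("#channels: ", paste(recording$labels, collapse = ",")),
               paste0("#dims: ", paste(d, collapse = " "))), con)
  for (e in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      writeLines(paste(sprintf("%.17g", recording$epochs[e, ch, ]),
                       collapse = " "), con)
    }
  }
  invisible(path)
}

#' @rdname write_epochs
#' @param layout Optional `wnet_layout` to attach (labels must match).
#' @export
read_epochs <- function(path, layout = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^#", key, ": "), "",
                           grep(paste0("^#", key, ":"), hdr, value = TRUE))
  subject <- get("subject")
  fs <- as.numeric(get("fs"))
  labels <- strsplit(get("channels"), ",")[[1]]
  dims <- as.integer(strsplit(get("dims"), " ")[[1]])
  body <- lines[!grepl("^#", lines)]
  if (length(body) != dims[1] * dims[2]) stop_invalid("corrupt epochs file")
  epochs <- array(0, dim = dims)
  idx <- 0L
  for (e in seq_len(dims[1])) {
    for (ch in seq_len(dims[2])) {
      idx <- idx + 1L
      epochs[e, ch, ] <- as.numeric(strsplit(body[idx], " ")[[1]])
    }
  }
  if (!is.null(layout)) {
    assert_layout(layout)
    if (!identical(as.character(layout$label), labels)) {
      stop_invalid("layout labels do not match epochs file channels")
    }
  }
  structure(list(subject_id = subject, epochs = epochs, fs = fs,
                 labels = labels, layout = layout), class = "wnet_recording")
}
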