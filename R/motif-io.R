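#' Read motifs from a JASPAR-style raw count file
#'
#' Accepts the classic JASPAR dialect: a `>id name` header followed by four
#' rows of counts, either bare numbers or `A [ 1 2 3 ]` bracketed rows. Rows
#' without base labels are assumed to be in A, C, G, T order.
#'
#' @param path File path.
#' @param background,pseudocount Passed to [pwm()].
#' @return List of `pwm` objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.375) {
  if (!file.exists(path)) stop(sprintf("motif file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop(sprintf("no '>' headers in %s", path))
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(hdr, "\\s+")[[1]][1]
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) < 4L)
      stop(sprintf("motif '%s': expected 4 count rows", id))
    rows <- lapply(body[1:4], function(ln) {
      ln <- gsub("[][]", " ", ln)
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      if (toupper(toks[1]) %in% DNA_BASES) toks <- toks[-1]
      vals <- suppressWarnings(as.numeric(toks))
      if (anyNA(vals))
        stop(sprintf("motif '%s': non-numeric count row", id))
      vals
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop(sprintf("motif '%s': ragged count rows", id))
    counts <- do.call(rbind, rows)
    labels <- toupper(substr(trimws(body[1:4]), 1, 1))
    if (all(labels %in% DNA_BASES) && !anyDuplicated(labels))
      counts <- counts[match(DNA_BASES, labels), , drop = FALSE]
    out[[i]] <- pwm(id, counts, background = background,
                    pseudocount = pseudocount)
  }
  out
}

#' Write motifs in JASPAR raw count format
#'
#' @param pwms List of `pwm` objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s", p$id), con)
    for (b in DNA_BASES) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read motifs from a MEME minimal-format file
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections and
#' the optional `Background letter frequencies` line. Probabilities are
#' rescaled to counts using the declared `nsites` (20 when absent).
#'
#' @param path File path.
#' @param pseudocount Passed to [pwm()].
#' @return List of `pwm` objects.
#' @export
read_meme <- function(path, pseudocount = 0.375) {
  if (!file.exists(path)) stop(sprintf("motif file not found: %s", path))
  lines <- readLines(path)
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    labs <- toupper(toks)
    pos <- match(DNA_BASES, labs)
    if (!anyNA(pos)) background <- vals[pos + 1L]
  }
  motif_at <- grep("^MOTIF\\b", lines)
  if (length(motif_at) == 0L) stop(sprintf("no MOTIF blocks in %s", path))
  out <- list()
  for (m in motif_at) {
    id <- strsplit(trimws(lines[m]), "\\s+")[[1]][2]
    lp <- grep("^letter-probability matrix", lines[m:length(lines)])[1] + m - 1L
    hdr <- lines[lp]
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr))
      as.numeric(sub(".*\\bnsites=\\s*([0-9.]+).*", "\\1", hdr)) else 20
    rows <- lines[(lp + 1L):(lp + w)]
    probs <- t(vapply(rows, function(ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]][1:4]), numeric(4)))
    counts <- t(probs) * nsites           # 4 x w
    out[[length(out) + 1L]] <- pwm(id, counts, background = background,
                                   pseudocount = pseudocount)
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param pwms List of `pwm` objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- pwms[[1]]$background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg["A"], bg["C"], bg["G"], bg["T"]), ""), con)
  for (p in pwms) {
    f <- pwm_freq(p)
    nsites <- max(colSums(p$counts))
    writeLines(sprintf("MOTIF %s", p$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %g E= 0",
      ncol(f), nsites), con)
    for (j in seq_len(ncol(f)))
      writeLines(paste(sprintf("%.6f", f[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a motif file, sniffing the dialect
#'
#' Files starting with a `MEME version` line are parsed as MEME minimal
#' format; anything with `>` headers as JASPAR raw counts.
#'
#' @param path File path.
#' @param ... Passed to the underlying reader.
#' @return List of `pwm` objects.
#' @export
read_motifs <- function(path, ...) {
  if (!file.exists(path)) stop(sprintf("motif file not found: %s", path))
  head1 <- readLines(path, n = 5L)
  if (any(grepl("^MEME version", head1))) read_meme(path, ...)
  else read_jaspar(path, ...)
}
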