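#' Read a WIF fragment file
#'
#' WIF (WhatsHap Input Format) encodes one read per line as entries
#' `<pos> <base> <allele> <phred>` separated by `" : "`, terminated by a
#' comment field `"# <score> : <name>"`.  Positions are 1-based genomic
#' coordinates, alleles are 0/1, and the phred integer is used directly as
#' the wMEC confidence weight.  Everything in the comment field except the
#' read name is ignored and not preserved.
#'
#' Reads covering fewer than two SNP columns cannot constrain phase; they
#' are retained but counted in a message.
#'
#' @param path file path or connection.
#' @return a [fragment_matrix()] whose columns are the sorted union of the
#'   positions seen.
#' @export
parse_wif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty WIF input")
  recs <- lapply(seq_along(lines), function(ln) {
    parts <- strsplit(lines[[ln]], "#", fixed = TRUE)[[1L]]
    if (length(parts) < 1L || !nzchar(trimws(parts[1L])))
      stop("WIF parse error at line ", ln, ": no entries before '#'")
    name <- NA_character_
    if (length(parts) >= 2L) {
      com <- strsplit(parts[2L], ":", fixed = TRUE)[[1L]]
      if (length(com) >= 2L) name <- trimws(com[2L])
    }
    fields <- strsplit(parts[1L], ":", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(trimws(fields))]
    ent <- lapply(fields, function(fld) {
      tok <- strsplit(trimws(fld), "[[:space:]]+")[[1L]]
      if (length(tok) != 4L)
        stop("WIF parse error at line ", ln,
             ": entry needs 'pos base allele phred', got '", fld, "'")
      pos <- suppressWarnings(as.integer(tok[1L]))
      allele <- tok[3L]
      phred <- suppressWarnings(as.numeric(tok[4L]))
      if (is.na(pos) || is.na(phred))
        stop("WIF parse error at line ", ln, ": non-numeric field in '",
             fld, "'")
      if (!allele %in% c("0", "1"))
        stop("WIF parse error at line ", ln, ": allele must be 0 or 1")
      list(pos = pos, allele = as.integer(allele), phred = phred)
    })
    pos <- vapply(ent, `[[`, integer(1), "pos")
    if (length(pos) > 1L && any(diff(pos) <= 0))
      stop("WIF parse error at line ", ln,
           ": positions must be strictly increasing within a read")
    list(pos = pos,
         allele = vapply(ent, `[[`, integer(1), "allele"),
         phred = vapply(ent, `[[`, numeric(1), "phred"),
         name = name)
  })
  positions <- sort(unique(unlist(lapply(recs, `[[`, "pos"))))
  m <- length(recs)
  n <- length(positions)
  entries <- matrix(NA_integer_, m, n)
  weights <- matrix(0, m, n)
  for (i in seq_len(m)) {
    j <- match(recs[[i]]$pos, positions)
    entries[i, j] <- recs[[i]]$allele
    weights[i, j] <- recs[[i]]$phred
  }
  ids <- vapply(recs, `[[`, character(1), "name")
  if (anyNA(ids) || anyDuplicated(ids)) ids <- paste0("read", seq_len(m))
  short <- sum(rowSums(!is.na(entries)) < 2L)
  if (short > 0L)
    message(short, " read(s) cover < 2 SNPs and cannot constrain phase")
  fragment_matrix(entries, weights, positions, ids)
}

#' Write a fragment matrix as WIF
#'
#' Inverse of [parse_wif()]; the base column is re-synthesized as `A` for
#' allele 0 and `C` for allele 1 (the wMEC model never uses it), and the
#' comment score is the read's mean phred weight.
#'
#' @param M a [fragment_matrix()].
#' @param path output file path or connection.
#' @export
write_wif <- function(M, path) {
  lines <- vapply(seq_len(nrow(M$entries)), function(i) {
    j <- which(!is.na(M$entries[i, ]))
    a <- M$entries[i, j]
    ent <- sprintf("%d %s %d %d", M$positions[j],
                   ifelse(a == 0L, "A", "C"), a,
                   as.integer(round(M$weights[i, j])))
    sprintf("%s : # %d : %s", paste(ent, collapse = " : "),
            as.integer(round(mean(M$weights[i, j]))), M$read_ids[i])
  }, character(1))
  writeLines(lines, path)
}

.hap_chars <- function(h) {
  out <- as.character(h)
  out[is.na(h)] <- "X"
  paste(out, collapse = "")
}

.parse_hap_line <- function(s, ln) {
  v <- strsplit(s, "")[[1L]]
  if (!all(v %in% c("0", "1", "X")))
    stop("haplotype line ", ln, " must contain only 0, 1, X")
  out <- suppressWarnings(as.integer(v))
  out
}

#' Write assembled haplotypes in block stanzas
#'
#' One stanza per block: a header `BLOCK <first_pos> <last_pos> <n_cols>
#' <cost>`, the two haplotype strings over \{0, 1, X\} (X = ambiguous,
#' masked), and the space-separated genomic positions.
#'
#' @param result a `hap_assembly` from [assemble()].
#' @param path output file path or connection.
#' @export
write_haplotypes <- function(result, path) {
  lines <- unlist(lapply(result$blocks, function(blk) {
    c(sprintf("BLOCK %d %d %d %d", min(blk$positions), max(blk$positions),
              length(blk$positions), as.integer(blk$cost)),
      .hap_chars(blk$h1), .hap_chars(blk$h2),
      paste(blk$positions, collapse = " "))
  }))
  writeLines(lines, path)
}

#' Read a block-structured haplotype file
#'
#' @param path file written by [write_haplotypes()].
#' @return list of blocks with `positions`, `h1`, `h2` (`NA` = masked) and
#'   `cost`.
#' @export
parse_haplotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^BLOCK ", lines)
  if (length(starts) == 0L) stop("no BLOCK stanzas found")
  lapply(starts, function(s) {
    hdr <- as.numeric(strsplit(lines[s], " ")[[1L]][-1L])
    h1 <- .parse_hap_line(lines[s + 1L], s + 1L)
    h2 <- .parse_hap_line(lines[s + 2L], s + 2L)
    positions <- as.integer(strsplit(lines[s + 3L], " ")[[1L]])
    if (length(h1) != length(h2) || length(h1) != length(positions))
      stop("block stanza at line ", s, " has inconsistent widths")
    list(positions = positions, h1 = h1, h2 = h2, cost = hdr[4L])
  })
}

#' Read a ground-truth haplotype pair
#'
#' Three lines: the two haplotype strings over \{0, 1\} and the
#' space-separated positions.
#'
#' @param path file path or connection.
#' @return list with `h1`, `h2`, `positions`.
#' @export
parse_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("truth file needs 2 haplotype lines + positions")
  h1 <- .parse_hap_line(lines[1L], 1L)
  h2 <- .parse_hap_line(lines[2L], 2L)
  if (anyNA(h1) || anyNA(h2)) stop("truth haplotypes must be unmasked")
  if (length(h1) != length(h2)) stop("truth haplotype length mismatch")
  positions <- as.integer(strsplit(lines[3L], " ")[[1L]])
  if (length(positions) != length(h1)) stop("positions length mismatch")
  list(h1 = h1, h2 = h2, positions = positions)
}

#' Write a ground-truth haplotype pair
#'
#' @param truth list with `h1`, `h2`, `positions`.
#' @param path output file path or connection.
#' @export
write_truth <- function(truth, path) {
  writeLines(c(paste(truth$h1, collapse = ""),
               paste(truth$h2, collapse = ""),
               paste(truth$positions, collapse = " ")), path)
}
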