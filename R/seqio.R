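#' Construct a protein multiple sequence alignment
#'
#' Light container for one protein's alignment: equal-length upper-case rows
#' over the 20 amino-acid letters, gap `-` and unknown `X`. `.` is normalized
#' to `-` on input.
#'
#' @param seqs Named character vector of aligned sequences (names are species
#'   identifiers) or a character matrix with one row per species.
#' @param protein Protein name carried as metadata (e.g. `"KaiA"`).
#' @return Object of class `kai_msa`: list with `protein`, `ids`, `seqs`
#'   (named character vector) and `n_col`.
#' @export
msa <- function(seqs, protein = "protein") {
  if (is.matrix(seqs)) {
    ids <- rownames(seqs)
    seqs <- apply(seqs, 1L, paste0, collapse = "")
    names(seqs) <- ids
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named by species identifier")
  if (anyDuplicated(names(seqs)))
    stop("duplicated species identifiers: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- names(seqs)[lens != lens[1L]]
    stop("ragged alignment: record(s) ", paste(bad, collapse = ", "),
         " differ in length from the first record")
  }
  ok <- paste0(c(AA_ALPHABET, "X", "-"), collapse = "")
  for (i in seq_along(seqs)) {
    hit <- regexpr(sprintf("[^%s]", ok), seqs[[i]])
    if (hit > 0L)
      stop(sprintf("illegal residue character '%s' in record '%s' column %d",
                   substr(seqs[[i]], hit, hit), names(seqs)[i], hit))
  }
  structure(list(protein = protein, ids = names(seqs), seqs = seqs,
                 n_col = unname(lens[1L])),
            class = "kai_msa")
}

#' @export
print.kai_msa <- function(x, ...) {
  cat(sprintf("<kai_msa> %s: %d species x %d columns\n",
              x$protein, length(x$ids), x$n_col))
  invisible(x)
}

# alignment as a species x column character matrix
msa_matrix <- function(x) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Read a protein alignment from FASTA or Clustal format
#'
#' Rows are upper-cased and `.` gaps normalized to `-`; species order is
#' preserved from the file. Ragged rows or illegal residue characters raise an
#' error naming the offending record.
#'
#' @param path File path.
#' @param format `"fasta"` or `"clustal"`.
#' @param protein Protein name stored in the returned alignment.
#' @return A [msa()] object.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           protein = "protein") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty alignment file: ", path)
  if (format == "fasta") {
    recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                               forceDNAtolower = FALSE)
    if (length(recs) == 0L) stop("no FASTA records in ", path)
    seqs <- vapply(recs, function(r) as.character(r)[1L], character(1))
    names(seqs) <- names(recs)
  } else {
    aln <- seqinr::read.alignment(path, format = "clustal")
    if (is.null(aln$nb) || aln$nb == 0L) stop("no Clustal records in ", path)
    seqs <- setNames(unlist(aln$seq), aln$nam)
  }
  msa(seqs, protein = protein)
}

#' Write a protein alignment to FASTA or Clustal format
#'
#' The Clustal writer emits a minimal CLUSTAL-format file (60-column blocks)
#' read back identically by [read_alignment()].
#'
#' @param x A [msa()] object.
#' @param path Output file path.
#' @param format `"fasta"` or `"clustal"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path, format = c("fasta", "clustal")) {
  stopifnot(inherits(x, "kai_msa"))
  format <- match.arg(format)
  if (format == "fasta") {
    seqinr::write.fasta(as.list(x$seqs), names = x$ids, file.out = path,
                        nbchar = 60)
  } else {
    width <- max(nchar(x$ids)) + 3L
    con <- file(path, "w"); on.exit(close(con))
    writeLines("CLUSTAL W (kaiabc)\n", con)
    # always emit at least two sequence blocks: standard Clustal readers
    # detect the end of the name table by the first repeated name
    block <- if (x$n_col > 60L) 60L else max(1L, ceiling(x$n_col / 2))
    starts <- seq(1L, x$n_col, by = block)
    for (s in starts) {
      e <- min(s + block - 1L, x$n_col)
      for (i in seq_along(x$ids))
        writeLines(sprintf("%-*s%s", width, x$ids[i],
                           substr(x$seqs[i], s, e)), con)
      # conservation line (blank), part of the standard block layout
      writeLines(strrep(" ", width + e - s + 1L), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Concatenate per-protein alignments into one multi-protein alignment
#'
#' Joins several alignments that share species into a single alignment with
#' per-protein column blocks, the container used for tree building and
#' co-variation scans. Under `"intersection"` species absent from any
#' alignment are dropped with a warning; under `"strict"` all alignments must
#' share an identical species set.
#'
#' @param msas List of [msa()] objects.
#' @param species_policy `"intersection"` or `"strict"`.
#' @return Object of class `kai_concat`: list with `ids`, `seqs`, `n_col`,
#'   `blocks` (data frame `protein`, `start`, `end`; 1-based inclusive column
#'   ranges) and an initially empty `ref_map` (see [build_ref_map()]).
#' @export
concatenate_alignments <- function(msas,
                                   species_policy = c("intersection", "strict")) {
  species_policy <- match.arg(species_policy)
  if (inherits(msas, "kai_msa")) msas <- list(msas)
  stopifnot(length(msas) >= 1L, all(vapply(msas, inherits, logical(1), "kai_msa")))
  prot <- vapply(msas, `[[`, character(1), "protein")
  if (anyDuplicated(prot)) stop("duplicated protein names in msas")
  idsets <- lapply(msas, `[[`, "ids")
  common <- Reduce(intersect, idsets)
  if (species_policy == "strict") {
    asym <- unique(unlist(lapply(idsets, function(s)
      c(setdiff(s, common), setdiff(common, s)))))
    extra <- unique(unlist(lapply(idsets, setdiff, y = common)))
    if (length(extra) > 0L)
      stop("strict species policy: species not shared by all alignments: ",
           paste(sort(extra), collapse = ", "))
  } else {
    dropped <- setdiff(unique(unlist(idsets)), common)
    if (length(dropped) > 0L)
      warning("dropping species absent from at least one alignment: ",
              paste(sort(dropped), collapse = ", "))
  }
  if (length(common) == 0L) stop("no species shared by all alignments")
  # keep the species order of the first alignment
  ids <- idsets[[1L]][idsets[[1L]] %in% common]
  widths <- vapply(msas, `[[`, numeric(1), "n_col")
  ends <- cumsum(widths)
  starts <- c(1, head(ends, -1) + 1)
  seqs <- vapply(ids, function(id)
    paste0(vapply(msas, function(m) unname(m$seqs[id]), character(1)),
           collapse = ""), character(1))
  structure(list(
    ids = ids, seqs = seqs, n_col = unname(ends[length(ends)]),
    blocks = data.frame(protein = prot, start = starts, end = ends),
    ref_map = NULL, reference_species = NULL),
    class = "kai_concat")
}

#' @export
print.kai_concat <- function(x, ...) {
  cat(sprintf("<kai_concat> %d species x %d columns (%s)\n",
              length(x$ids), x$n_col,
              paste(sprintf("%s:%d-%d", x$blocks$protein, x$blocks$start,
                            x$blocks$end), collapse = ", ")))
  if (!is.null(x$reference_species))
    cat("  residue numbering by reference species:", x$reference_species, "\n")
  invisible(x)
}

concat_matrix <- function(x) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

# protein of each column, from the block table
column_protein <- function(concat) {
  out <- character(concat$n_col)
  for (i in seq_len(nrow(concat$blocks)))
    out[concat$blocks$start[i]:concat$blocks$end[i]] <- concat$blocks$protein[i]
  out
}

#' Number alignment columns by a reference sequence
#'
#' Assigns, per protein block, consecutive 1-based residue numbers of the
#' chosen reference species to the columns where that species has a non-gap
#' character (the convention used for residue labels such as KaiC-495). Gap
#' columns of the reference carry no number.
#'
#' @param concat A [concatenate_alignments()] object.
#' @param reference_species Species identifier present in `concat`.
#' @return `concat` with `ref_map` filled: data frame `col`, `protein`,
#'   `ref_number` (`NA` for reference-gap columns).
#' @export
build_ref_map <- function(concat, reference_species) {
  stopifnot(inherits(concat, "kai_concat"))
  if (!reference_species %in% concat$ids)
    stop("reference species not in alignment: ", reference_species)
  refrow <- strsplit(concat$seqs[[reference_species]], "", fixed = TRUE)[[1L]]
  prot <- column_protein(concat)
  num <- rep(NA_integer_, concat$n_col)
  for (i in seq_len(nrow(concat$blocks))) {
    idx <- concat$blocks$start[i]:concat$blocks$end[i]
    nongap <- refrow[idx] != "-"
    num[idx[nongap]] <- seq_len(sum(nongap))
  }
  if (all(is.na(num)))
    warning("reference sequence is all gaps; empty residue numbering")
  concat$ref_map <- data.frame(col = seq_len(concat$n_col), protein = prot,
                               ref_number = num)
  concat$reference_species <- reference_species
  concat
}

# "KaiA-239"-style label for a column; bare column number if unnumbered
column_label <- function(concat, col) {
  if (is.null(concat$ref_map)) return(sprintf("col%d", col))
  rn <- concat$ref_map$ref_number[col]
  pr <- concat$ref_map$protein[col]
  ifelse(is.na(rn), sprintf("%s-col%d", pr, col), sprintf("%s-%d", pr, rn))
}

#' Gap fraction and residue diversity of an alignment column
#'
#' `gap_fraction` counts gaps and unknown (`X`) residues; `n_distinct` counts
#' distinct standard amino-acid types only. These are the quantities the
#' co-variation column filters operate on.
#'
#' @param concat A [concatenate_alignments()] object.
#' @param col Column index (1-based).
#' @return List with `gap_fraction` and `n_distinct`.
#' @export
column_stats <- function(concat, col) {
  stopifnot(inherits(concat, "kai_concat"))
  if (length(col) != 1L || col < 1L || col > concat$n_col)
    stop("column index out of range: ", col)
  chars <- substr(concat$seqs, col, col)
  gap <- chars %in% GAP_CHARS
  list(gap_fraction = mean(gap),
       n_distinct = length(unique(chars[!gap])))
}

#' Per-column summary table of a concatenated alignment
#'
#' @param concat A [concatenate_alignments()] object (optionally with a
#'   reference map).
#' @return Data frame with one row per column: `col`, `protein`, `ref_number`,
#'   `gap_fraction`, `n_distinct`.
#' @export
alignment_report <- function(concat) {
  stopifnot(inherits(concat, "kai_concat"))
  m <- concat_matrix(concat)
  gap <- matrix(m %in% GAP_CHARS, nrow = nrow(m))
  gf <- colMeans(gap)
  nd <- vapply(seq_len(ncol(m)), function(j)
    length(unique(m[!gap[, j], j])), integer(1))
  rn <- if (is.null(concat$ref_map)) NA_integer_ else concat$ref_map$ref_number
  data.frame(col = seq_len(concat$n_col), protein = column_protein(concat),
             ref_number = rn, gap_fraction = gf, n_distinct = nd)
}
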