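#' Residue-residue contact map from atomic coordinates
#'
#' Two residues are in contact when the minimum distance between their
#' side-chain heavy atoms is at most `cutoff` (4.5 Angstroms by default, the
#' standard side-chain contact definition). Backbone atoms (N, CA, C, O, OXT)
#' are excluded; for glycine — or any residue whose side-chain atoms are
#' missing — the C-alpha is used as fallback (with a warning for non-glycine
#' residues). Inter-chain pairs and intra-chain pairs with sequence
#' separation of at least 2 are both recorded.
#'
#' @param pdb Path to a PDB file, or a `bio3d` `pdb` object.
#' @param cutoff Contact distance cutoff in Angstroms.
#' @param chain_to_protein Named character vector mapping chain identifiers to
#'   protein names (e.g. `c(A = "KaiA", B = "KaiA", C = "KaiC")`). Chains not
#'   in the mapping are ignored. `NULL` uses chain ids as protein names.
#' @return Data frame of class `kai_contacts`: `protein_i`, `res_i`,
#'   `protein_j`, `res_j`, `distance`; symmetric pairs stored once with
#'   `(protein_i, res_i) <= (protein_j, res_j)` lexicographically.
#' @export
contact_map <- function(pdb, cutoff = 4.5, chain_to_protein = NULL) {
  stopifnot(cutoff > 0)
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elesy != "H", , drop = FALSE]
  if (!is.null(chain_to_protein)) {
    at <- at[at$chain %in% names(chain_to_protein), , drop = FALSE]
    at$protein <- unname(chain_to_protein[at$chain])
  } else at$protein <- at$chain
  if (nrow(at) == 0L) stop("no atoms left after chain filtering")
  backbone <- c("N", "CA", "C", "O", "OXT")
  key <- paste(at$protein, at$chain, at$resno)
  res <- unique(data.frame(key = key, protein = at$protein, chain = at$chain,
                           resno = at$resno, resid = at$resid,
                           stringsAsFactors = FALSE))
  coords <- vector("list", nrow(res))
  for (i in seq_len(nrow(res))) {
    sub <- at[key == res$key[i], , drop = FALSE]
    side <- sub[!(sub$elety %in% backbone), , drop = FALSE]
    if (nrow(side) == 0L) {
      if (res$resid[i] != "GLY")
        warning("no side-chain atoms for ", res$protein[i], "-", res$resno[i],
                "; falling back to CA")
      side <- sub[sub$elety == "CA", , drop = FALSE]
    }
    coords[[i]] <- as.matrix(side[, c("x", "y", "z")])
  }
  out <- list(); n <- 0L
  for (i in seq_len(nrow(res) - 1L)) for (j in (i + 1L):nrow(res)) {
    same_chain <- res$chain[i] == res$chain[j]
    if (same_chain && abs(res$resno[i] - res$resno[j]) < 2L) next
    a <- coords[[i]]; b <- coords[[j]]
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
    dmin <- sqrt(max(0, min(d2)))
    if (dmin <= cutoff) {
      n <- n + 1L
      out[[n]] <- data.frame(protein_i = res$protein[i], res_i = res$resno[i],
                             protein_j = res$protein[j], res_j = res$resno[j],
                             distance = dmin)
    }
  }
  out <- if (n == 0L) data.frame(protein_i = character(), res_i = integer(),
                                 protein_j = character(), res_j = integer(),
                                 distance = numeric())
         else do.call(rbind, out)
  # canonical orientation so the map is order-independent
  flip <- paste(out$protein_i, out$res_i) > paste(out$protein_j, out$res_j)
  if (any(flip)) {
    tmp <- out[flip, ]
    out[flip, c("protein_i", "res_i")] <- tmp[, c("protein_j", "res_j")]
    out[flip, c("protein_j", "res_j")] <- tmp[, c("protein_i", "res_i")]
  }
  structure(out, class = c("kai_contacts", "data.frame"), cutoff = cutoff)
}

residue_key <- function(protein, res) paste0(protein, "-", res)

in_contact <- function(contacts, protein_i, res_i, protein_j, res_j) {
  a <- residue_key(protein_i, res_i); b <- residue_key(protein_j, res_j)
  have <- paste(residue_key(contacts$protein_i, contacts$res_i),
                residue_key(contacts$protein_j, contacts$res_j))
  paste(a, b) %in% have | paste(b, a) %in% have
}

#' Assemble contact-restricted co-varying residue clusters
#'
#' Builds a graph whose vertices are residues and whose edges are column
#' pairs that are both significantly correlated (on any property scale) and
#' in structural contact; clusters are the connected components with at least
#' two members. The assembly uses significance only — the sign of the
#' correlation is kept in the supporting records but does not affect
#' clustering.
#'
#' @param records A [scan_pairs()] result (rows with `significant == TRUE`
#'   are used). Residues are identified by `label_i`/`label_j` of the form
#'   `"Protein-Number"`, i.e. a reference map must have been built.
#' @param contacts A [contact_map()].
#' @return List of clusters, each a list with `id`, `members` (data frame
#'   `protein`, `ref_number`) and `records` (supporting correlation rows);
#'   classed `kai_clusters`.
#' @export
assemble_clusters <- function(records, contacts) {
  stopifnot(inherits(contacts, "kai_contacts"))
  sig <- records[!is.na(records$significant) & records$significant, ,
                 drop = FALSE]
  parse_label <- function(lab) {
    m <- regmatches(lab, regexec("^(.*)-(\\d+)$", lab))
    t(vapply(m, function(g) g[2:3], character(2)))
  }
  if (nrow(sig) > 0L) {
    pi_ <- parse_label(sig$label_i); pj <- parse_label(sig$label_j)
    okl <- !is.na(pi_[, 1L]) & !is.na(pj[, 1L])
    sig <- sig[okl, , drop = FALSE]
    pi_ <- pi_[okl, , drop = FALSE]; pj <- pj[okl, , drop = FALSE]
    touch <- in_contact(contacts, pi_[, 1L], as.integer(pi_[, 2L]),
                        pj[, 1L], as.integer(pj[, 2L]))
    sig <- sig[touch, , drop = FALSE]
    pi_ <- pi_[touch, , drop = FALSE]; pj <- pj[touch, , drop = FALSE]
  }
  if (nrow(sig) == 0L)
    return(structure(list(), class = "kai_clusters"))
  va <- residue_key(pi_[, 1L], pi_[, 2L])
  vb <- residue_key(pj[, 1L], pj[, 2L])
  g <- igraph::graph_from_data_frame(
    data.frame(from = va, to = vb), directed = FALSE)
  comp <- igraph::components(g)
  ord <- order(-comp$csize)  # largest first for stable ids
  clusters <- list()
  cid <- 0L
  for (ci in seq_along(comp$csize)[ord]) {
    memb <- names(comp$membership)[comp$membership == ci]
    if (length(memb) < 2L) next
    cid <- cid + 1L
    parts <- parse_label(memb)
    mdf <- data.frame(protein = parts[, 1L],
                      ref_number = as.integer(parts[, 2L]))
    mdf <- mdf[order(mdf$protein, mdf$ref_number), ]
    rownames(mdf) <- NULL
    keep <- va %in% memb & vb %in% memb
    clusters[[cid]] <- list(id = cid, members = mdf,
                            records = sig[keep, , drop = FALSE])
  }
  structure(clusters, class = "kai_clusters")
}

#' @export
print.kai_clusters <- function(x, ...) {
  cat(sprintf("<kai_clusters> %d cluster(s)\n", length(x)))
  for (cl in x)
    cat(sprintf("  %d: %s\n", cl$id,
                paste(residue_key(cl$members$protein, cl$members$ref_number),
                      collapse = ", ")))
  invisible(x)
}
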