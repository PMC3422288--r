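#' Assemble reads into contigs
#'
#' De novo assembly of the pooled mutant reads.  The builtin backend is a
#' compact de Bruijn assembler written for hermetic simulation runs: it
#' counts (k+1)-mers on both strands, drops low-coverage k-mers (sequencing
#' errors), condenses unambiguous paths into unitigs, clips short dead-end
#' tips, and merges "bubbles" — parallel paths between the same junctions —
#' only when the two paths diverge by at most `max_divergence`.  Bubbles
#' more diverged than that are left intact on purpose: in a mutagenized
#' pool each mutant type differs from its siblings by around the mutation
#' load, and keeping those bubbles separate is what lets every mutant come
#' out as its own contig.  The long default k-mer (90) buys specificity at
#' the cost of needing generous coverage.
#'
#' A `"velvet"` backend is provided as a thin adapter around the Velvet
#' binaries (`velveth`/`velvetg`, with hash length `k`,
#' `-cov_cutoff`/`-exp_cov auto`, `-min_contig_lgth` and `-max_divergence`)
#' for fidelity runs on systems where Velvet is installed; it is not
#' required by any builtin functionality.
#'
#' @param reads an `ngsam_read_pairs`, a [Biostrings::DNAStringSet] or a
#'   character vector of reads (pairs are treated as single-end reads: the
#'   consensus procedure operates on contigs and does not need mate
#'   resolution).
#' @param k k-mer length (default 90; must be shorter than the reads).
#' @param min_contig drop contigs shorter than this (default 400).
#' @param max_divergence merge parallel bubble paths only when their
#'   divergence is at most this fraction (default 0.1).
#' @param backend `"builtin"` or `"velvet"`.
#' @param cov_cutoff minimum (k+1)-mer count retained; `NULL` (default)
#'   estimates expected coverage as the count-weighted median and uses 10%
#'   of it (at least 1).
#' @return object of class `ngsam_contigs`: list with `contigs` (character
#'   vector, names `contig1..n`), `coverage` (mean k-mer support per
#'   contig) and `backend`.
#' @section Failure: signals `ngsam_assembly_failure` when no contig of at
#'   least `min_contig` bp survives.
#' @export
assemble <- function(reads, k = 90L, min_contig = 400L,
                     max_divergence = 0.1,
                     backend = c("builtin", "velvet"),
                     cov_cutoff = NULL) {
  backend <- match.arg(backend)
  seqs <- reads_as_character(reads)
  if (length(seqs) == 0L) assembly_failure("no reads to assemble")
  if (k >= max(nchar(seqs))) {
    stop("k must be smaller than the read length", call. = FALSE)
  }
  if (backend == "velvet") {
    return(assemble_velvet(seqs, k, min_contig, max_divergence))
  }
  assemble_builtin(seqs, k, min_contig, max_divergence, cov_cutoff)
}

reads_as_character <- function(reads) {
  if (inherits(reads, "ngsam_read_pairs")) {
    c(as.character(reads$read1), as.character(reads$read2))
  } else if (methods::is(reads, "DNAStringSet")) {
    as.character(reads)
  } else {
    as.character(reads)
  }
}

assemble_builtin <- function(seqs, k, min_contig, max_divergence,
                             cov_cutoff) {
  both <- c(seqs, revcomp(seqs))
  km <- extract_kmers(both, k + 1L)
  dt <- data.table::as.data.table(list(km = km))[, list(N = .N), by = "km"]
  if (is.null(cov_cutoff)) {
    ## count-weighted median of (k+1)-mer multiplicities ~ per-type coverage
    o <- order(dt$N)
    cum <- cumsum(as.numeric(dt$N[o]))
    exp_cov <- dt$N[o][which(cum >= cum[length(cum)] / 2)[1L]]
    cov_cutoff <- max(1, ceiling(0.1 * exp_cov))
  }
  dt <- dt[dt$N >= cov_cutoff, ]
  if (nrow(dt) == 0L) assembly_failure("no k-mers above the coverage cutoff")

  g <- kmer_graph(dt$km, dt$N, k)
  for (round in 1:3) {
    uni <- condense_unitigs(g, k)
    drop <- clip_tips(g, uni, k)
    drop <- c(drop, pop_bubbles(g, uni, max_divergence))
    if (length(drop) == 0L) break
    keep <- !(uni$edge_unitig %in% drop)
    g <- kmer_graph_sub(g, keep)
    if (length(g$ui) == 0L) assembly_failure("graph empty after cleaning")
  }
  uni <- condense_unitigs(g, k)
  lens <- nchar(uni$seq)
  keep <- lens >= min_contig
  if (!any(keep)) {
    assembly_failure(sprintf("no contig reached min_contig = %d", min_contig))
  }
  contigs <- uni$seq[keep]
  covs <- uni$cov[keep]
  ## both strands were assembled; keep one orientation per contig
  rc <- revcomp(contigs)
  canon <- ifelse(contigs < rc, contigs, rc)
  first <- !duplicated(canon)
  contigs <- contigs[first]
  covs <- covs[first]
  o <- order(nchar(contigs), decreasing = TRUE)
  contigs <- contigs[o]
  covs <- covs[o]
  names(contigs) <- paste0("contig", seq_along(contigs))
  structure(list(contigs = contigs, coverage = covs, backend = "builtin"),
            class = "ngsam_contigs")
}

extract_kmers <- function(seqs, klen) {
  w <- nchar(seqs)
  out <- vector("list", max(w) - klen + 1L)
  for (j in seq_along(out)) {
    s <- substring(seqs, j, j + klen - 1L)
    out[[j]] <- s[nchar(s) == klen]
  }
  unlist(out, use.names = FALSE)
}

## edge-centric de Bruijn graph over the retained (k+1)-mers
kmer_graph <- function(k1mers, weight, k) {
  u <- substring(k1mers, 1L, k)
  v <- substring(k1mers, 2L, k + 1L)
  nodes <- unique(c(u, v))
  g <- list(nodes = nodes,
            ui = match(u, nodes), vi = match(v, nodes),
            w = as.numeric(weight))
  g$outdeg <- tabulate(g$ui, length(nodes))
  g$indeg <- tabulate(g$vi, length(nodes))
  g
}

kmer_graph_sub <- function(g, keep_edges) {
  ui <- g$ui[keep_edges]
  vi <- g$vi[keep_edges]
  used <- sort(unique(c(ui, vi)))
  g2 <- list(nodes = g$nodes[used],
             ui = match(ui, used), vi = match(vi, used),
             w = g$w[keep_edges])
  g2$outdeg <- tabulate(g2$ui, length(used))
  g2$indeg <- tabulate(g2$vi, length(used))
  g2
}

## condense maximal unambiguous paths; returns unitig table plus the
## unitig membership of every edge (used for clipping/popping)
condense_unitigs <- function(g, k) {
  n_edges <- length(g$ui)
  ## a unitig is a maximal chain of edges linked through nodes with
  ## in-degree 1 and out-degree 1; edge f follows e when f starts where e
  ## ends and the shared node is such a through-node
  out_edge <- rep(NA_integer_, length(g$nodes))
  single_out <- g$outdeg[g$ui] == 1L
  out_edge[g$ui[single_out]] <- which(single_out)
  thru <- g$indeg == 1L & g$outdeg == 1L
  nxt <- rep(NA_integer_, n_edges)
  ok <- thru[g$vi]
  nxt[ok] <- out_edge[g$vi[ok]]
  has_prev <- rep(FALSE, n_edges)
  has_prev[nxt[!is.na(nxt)]] <- TRUE
  visited <- rep(FALSE, n_edges)
  chains <- list()
  edge_unitig <- integer(n_edges)
  uid <- 0L
  buf <- integer(n_edges)
  for (e0 in c(which(!has_prev), seq_len(n_edges))) {  # chain heads, then cycles
    if (visited[e0]) next
    len <- 0L
    e <- e0
    while (!is.na(e) && !visited[e]) {
      visited[e] <- TRUE
      len <- len + 1L
      buf[len] <- e
      e <- nxt[e]
    }
    chain <- buf[seq_len(len)]
    uid <- uid + 1L
    chains[[uid]] <- chain
    edge_unitig[chain] <- uid
  }
  res_seq <- vapply(chains, function(chain) {
    paste0(g$nodes[g$ui[chain[1L]]],
           paste(substring(g$nodes[g$vi[chain]], k, k), collapse = ""))
  }, character(1))
  list(seq = res_seq,
       cov = vapply(chains, function(ch) mean(g$w[ch]), numeric(1)),
       first = vapply(chains, function(ch) g$ui[ch[1L]], integer(1)),
       last = vapply(chains, function(ch) g$vi[ch[length(ch)]], integer(1)),
       edge_unitig = edge_unitig)
}

## tips: unitigs dead at exactly one end and shorter than 2k
clip_tips <- function(g, uni, k) {
  n_uni <- length(uni$seq)
  if (n_uni == 0L) return(integer(0))
  dead_start <- g$indeg[uni$first] == 0L
  dead_end <- g$outdeg[uni$last] == 0L
  tip <- xor(dead_start, dead_end) & nchar(uni$seq) < 2L * k
  which(tip)
}

## bubbles: unitig pairs sharing both junction nodes; merge when divergence
## is at or below the threshold, keeping the better-covered path
pop_bubbles <- function(g, uni, max_divergence) {
  n_uni <- length(uni$seq)
  if (n_uni < 2L) return(integer(0))
  key <- paste(uni$first, uni$last)
  drop <- integer(0)
  for (grp in split(seq_len(n_uni), key)) {
    if (length(grp) < 2L) next
    grp <- grp[order(uni$cov[grp], decreasing = TRUE)]
    keepidx <- grp[1L]
    for (i in grp[-1L]) {
      if (seq_divergence(uni$seq[keepidx], uni$seq[i]) <= max_divergence) {
        drop <- c(drop, i)
      }
    }
  }
  drop
}

## fraction of differing positions under a global alignment
seq_divergence <- function(a, b) {
  if (a == b) return(0)
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = ngsam_submat(),
                                      gapOpening = 10, gapExtension = 4)
  1 - Biostrings::nmatch(al) / max(nchar(a), nchar(b))
}

assemble_velvet <- function(seqs, k, min_contig, max_divergence) {
  velveth <- Sys.which("velveth")
  velvetg <- Sys.which("velvetg")
  if (velveth == "" || velvetg == "") {
    stop("velvet backend requested but velveth/velvetg not found on PATH",
         call. = FALSE)
  }
  dir <- tempfile("velvet")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  fa <- file.path(dir, "reads.fa")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- paste0("r", seq_along(x))
  Biostrings::writeXStringSet(x, fa)
  system2(velveth, c(dir, k, "-fasta", "-short", fa), stdout = FALSE)
  system2(velvetg, c(dir, "-exp_cov", "auto",
                     "-min_contig_lgth", min_contig,
                     "-max_divergence", max_divergence), stdout = FALSE)
  out <- file.path(dir, "contigs.fa")
  if (!file.exists(out)) assembly_failure("velvet produced no contigs")
  contigs <- as.character(Biostrings::readDNAStringSet(out))
  if (length(contigs) == 0L) assembly_failure("velvet produced no contigs")
  names(contigs) <- paste0("contig", seq_along(contigs))
  structure(list(contigs = contigs, coverage = rep(NA_real_, length(contigs)),
                 backend = "velvet"),
            class = "ngsam_contigs")
}

#' @export
print.ngsam_contigs <- function(x, ...) {
  cat(sprintf("<ngsam_contigs> %d contigs (%d-%d bp), backend %s\n",
              length(x$contigs), min(nchar(x$contigs)),
              max(nchar(x$contigs)), x$backend))
  invisible(x)
}

#' Write contigs as FASTA
#'
#' @param contigs an `ngsam_contigs` (or named character vector).
#' @param path output path.
#' @export
write_contigs <- function(contigs, path) {
  seqs <- if (inherits(contigs, "ngsam_contigs")) contigs$contigs else contigs
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
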