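# Sequence similarity networks and connected-component clustering.
#
# All-vs-all local protein alignment is delegated to NCBI BLAST+ (blastp)
# with the database fixed to the query set itself, so E-values are
# reproducible for a given sequence set. Edges passing the e-value and
# percent-identity thresholds define an undirected graph whose connected
# components are the sequence clusters; single-linkage transitivity is
# deliberate (it is what "same connected component" means).

.edge_proto <- data.frame(seq_a = character(), seq_b = character(),
                          evalue = numeric(), identity_pct = numeric(),
                          stringsAsFactors = FALSE)

.assign_proto <- data.frame(seq_id = character(), cluster = character(),
                            role = character(), stringsAsFactors = FALSE)

#' All-vs-all protein similarity edges
#'
#' Runs blastp of the sequence set against itself (database = the set) and
#' keeps, for every unordered pair with at least one alignment in either
#' direction, the best alignment's e-value and percent identity (best =
#' smallest e-value, ties by larger identity). Self-comparisons are
#' excluded. The union over both query/subject directions keeps the graph
#' independent of aligner output asymmetries.
#'
#' @param seqs named character vector of protein sequences (names are
#'   sequence ids, unique).
#' @param max_target_seqs cap on blastp subjects per query; raise for sets
#'   larger than the default 5000.
#' @param verbose log aligner version.
#' @return data.frame of canonical edges (`seq_a < seq_b`).
#' @export
pairwise_similarity <- function(seqs, max_target_seqs = 5000L,
                                verbose = FALSE) {
  if (length(seqs) == 0L) return(empty_df(.edge_proto))
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  blastp <- find_tool("blastp", "all-vs-all protein alignment")
  makeblastdb <- find_tool("makeblastdb", "BLAST database construction")
  dir <- tempfile("ssn")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  fa <- file.path(dir, "seqs.faa")
  write_fasta(seqs, fa)
  db <- file.path(dir, "db")
  ok <- system2(makeblastdb, c("-in", shQuote(fa), "-dbtype", "prot",
                               "-out", shQuote(db)),
                stdout = FALSE, stderr = FALSE)
  if (!identical(ok, 0L) && !identical(ok, 0))
    stop("makeblastdb failed (exit status ", ok, ")")
  out <- file.path(dir, "hits.tsv")
  ok <- system2(blastp, c("-query", shQuote(fa), "-db", shQuote(db),
                          "-outfmt", shQuote("6 qseqid sseqid pident evalue"),
                          "-evalue", "10",
                          "-max_target_seqs", max_target_seqs,
                          "-out", shQuote(out)),
                stdout = FALSE, stderr = FALSE)
  if (!identical(ok, 0L) && !identical(ok, 0))
    stop("blastp failed (exit status ", ok, ")")
  if (verbose) message("blastp (", tool_version("blastp"), ")")
  tab <- tryCatch(utils::read.table(out, sep = "\t", stringsAsFactors = FALSE,
                                    col.names = c("q", "s", "pident",
                                                  "evalue")),
                  error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0L) return(empty_df(.edge_proto))
  tab <- tab[tab$q != tab$s, , drop = FALSE]
  if (nrow(tab) == 0L) return(empty_df(.edge_proto))
  a <- pmin(tab$q, tab$s); b <- pmax(tab$q, tab$s)
  tab$seq_a <- a; tab$seq_b <- b
  tab <- tab[order(tab$seq_a, tab$seq_b, tab$evalue, -tab$pident), ,
             drop = FALSE]
  key <- paste(tab$seq_a, tab$seq_b, sep = "\r")
  best <- tab[!duplicated(key), , drop = FALSE]
  out_df <- data.frame(seq_a = best$seq_a, seq_b = best$seq_b,
                       evalue = best$evalue, identity_pct = best$pident,
                       stringsAsFactors = FALSE)
  rownames(out_df) <- NULL
  out_df
}

#' Build a sequence similarity network
#'
#' Nodes are all sequence ids (singletons included); an edge is kept iff its
#' e-value is at most `max_evalue` and its percent identity at least
#' `min_identity`.
#'
#' @param seq_ids character vector of all node ids.
#' @param edges edge data.frame from [pairwise_similarity()].
#' @param max_evalue e-value threshold (default 0.01).
#' @param min_identity percent-identity threshold (default 30).
#' @return an [igraph][igraph::graph_from_data_frame] undirected graph.
#' @export
build_ssn <- function(seq_ids, edges, max_evalue = 0.01, min_identity = 30) {
  seq_ids <- unique(as.character(seq_ids))
  if (nrow(edges)) {
    keep <- edges$evalue <= max_evalue & edges$identity_pct >= min_identity &
      edges$seq_a %in% seq_ids & edges$seq_b %in% seq_ids
    edges <- edges[keep, , drop = FALSE]
  }
  igraph::graph_from_data_frame(edges[, c("seq_a", "seq_b"), drop = FALSE],
                                directed = FALSE,
                                vertices = data.frame(name = seq_ids))
}

#' Cluster an SSN into labelled connected components
#'
#' Components are ordered by decreasing size, ties by the lexicographically
#' smallest member id, and labelled alphabetically (`"a","b",...` for hits,
#' `"A","B",...` for partners, continuing `"A1",...` past 26). The ordering
#' makes labels invariant under permutation of the input sequences.
#'
#' @param graph an SSN from [build_ssn()].
#' @param role cluster role recorded in the assignment: one of `"hit"`,
#'   `"partner_up"`, `"partner_down"`, `"partner_pooled"`, `"discarded"`.
#' @param case label alphabet case; defaults to lower for the hit role,
#'   upper otherwise.
#' @return assignment data.frame (`seq_id`, `cluster`, `role`).
#' @export
ssn_components <- function(graph, role = "hit",
                           case = if (role == "hit") "lower" else "upper") {
  n <- igraph::vcount(graph)
  if (n == 0L) return(empty_df(.assign_proto))
  comp <- igraph::components(graph)
  ids <- igraph::V(graph)$name
  members <- split(ids, comp$membership)
  first <- vapply(members, function(m) sort(m)[1L], character(1))
  ord <- order(-lengths(members), first)
  members <- members[ord]
  labels <- cluster_label(seq_along(members), case = case)
  out <- data.frame(
    seq_id = unlist(members, use.names = FALSE),
    cluster = rep(labels, lengths(members)),
    role = role, stringsAsFactors = FALSE)
  out <- out[order(out$seq_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster a set of protein sequences
#'
#' Convenience wrapper: [pairwise_similarity()] then [build_ssn()] then
#' [ssn_components()].
#'
#' @inheritParams pairwise_similarity
#' @inheritParams build_ssn
#' @inheritParams ssn_components
#' @return assignment data.frame.
#' @export
cluster_sequences <- function(seqs, role = "hit", max_evalue = 0.01,
                              min_identity = 30,
                              case = if (role == "hit") "lower" else "upper") {
  if (length(seqs) == 0L) return(empty_df(.assign_proto))
  edges <- pairwise_similarity(seqs)
  g <- build_ssn(names(seqs), edges, max_evalue, min_identity)
  ssn_components(g, role = role, case = case)
}

#' Split partner sequences into networks by orientation
#'
#' Orientation `either` (and single-sided `upstream`/`downstream`) pools
#' upstream and downstream partners into one network; `both` clusters the
#' upstream and downstream partners separately.
#'
#' @param operons operon data.frame from [filter_operons()].
#' @param orientation the orientation requirement used in filtering.
#' @return named list of named protein vectors: `partner_pooled`, or
#'   `partner_up` + `partner_down`.
#' @export
partition_partner_networks <- function(operons, orientation) {
  up <- operons[!is.na(operons$partner_up_orf_id),
                c("partner_up_orf_id", "partner_up_protein")]
  dn <- operons[!is.na(operons$partner_down_orf_id),
                c("partner_down_orf_id", "partner_down_protein")]
  up_v <- stats::setNames(up$partner_up_protein, up$partner_up_orf_id)
  dn_v <- stats::setNames(dn$partner_down_protein, dn$partner_down_orf_id)
  dedup <- function(v) v[!duplicated(names(v))]
  if (orientation == "both") {
    list(partner_up = dedup(up_v), partner_down = dedup(dn_v))
  } else {
    list(partner_pooled = dedup(c(up_v, dn_v)))
  }
}

#' Label operons with their hit and partner clusters
#'
#' The operon-type label concatenates the partner cluster label(s) (upstream
#' first, where present) and the hit cluster label, hyphen-separated — e.g.
#' a hit in cluster `a` with one partner in cluster `A` is operon type
#' `"A-a"`. Operons are "the same type" iff their labels match exactly.
#'
#' @param operons operon data.frame.
#' @param hit_assign hit-cluster assignment (role `"hit"`).
#' @param partner_assigns list of partner assignments from clustering the
#'   networks of [partition_partner_networks()].
#' @return `operons` with added columns `hit_cluster`,
#'   `partner_up_cluster`, `partner_down_cluster`, `operon_type`.
#' @export
label_operons <- function(operons, hit_assign, partner_assigns) {
  partner_all <- do.call(rbind, partner_assigns)
  lookup <- function(assign, ids, role = NULL) {
    if (is.null(assign) || nrow(assign) == 0L)
      return(rep(NA_character_, length(ids)))
    sub <- if (is.null(role)) assign else assign[assign$role %in% role, ]
    sub$cluster[match(ids, sub$seq_id)]
  }
  operons$hit_cluster <- lookup(hit_assign, operons$hit_orf_id)
  operons$partner_up_cluster <-
    lookup(partner_all, operons$partner_up_orf_id,
           c("partner_pooled", "partner_up"))
  operons$partner_down_cluster <-
    lookup(partner_all, operons$partner_down_orf_id,
           c("partner_pooled", "partner_down"))
  if (nrow(operons)) {
    unresolved <- (is.na(operons$hit_cluster)) |
      (!is.na(operons$partner_up_orf_id) & is.na(operons$partner_up_cluster)) |
      (!is.na(operons$partner_down_orf_id) &
         is.na(operons$partner_down_cluster))
    if (any(unresolved))
      stop("internal consistency error: ", sum(unresolved),
           " operon(s) reference sequences missing from the clustering")
    operons$operon_type <- vapply(seq_len(nrow(operons)), function(i) {
      paste(stats::na.omit(c(operons$partner_up_cluster[i],
                             operons$partner_down_cluster[i],
                             operons$hit_cluster[i])), collapse = "-")
    }, character(1))
  } else {
    operons$operon_type <- character(0)
  }
  operons
}

#' Cluster discarded hits and map them to accepted hit clusters
#'
#' Discarded hit sequences are clustered in their own SSN under the same
#' thresholds. Every discarded component is then compared against the
#' accepted hit sequences (same thresholds); a component with at least one
#' qualifying pairing is labelled `"<accepted-cluster>_discarded"` (the best
#' e-value decides between several accepted clusters), otherwise it gets a
#' fresh `"X<i>_discarded"` label. This surfaces broken or structurally
#' atypical loci of families that elsewhere form accepted operons.
#'
#' @param discarded_seqs named protein vector of discarded hit sequences.
#' @param accepted_seqs named protein vector of accepted hit sequences.
#' @param hit_assign accepted hit-cluster assignment.
#' @inheritParams build_ssn
#' @return assignment data.frame (role `"discarded"`).
#' @export
map_discarded <- function(discarded_seqs, accepted_seqs, hit_assign,
                          max_evalue = 0.01, min_identity = 30) {
  if (length(discarded_seqs) == 0L) return(empty_df(.assign_proto))
  stopifnot(!anyDuplicated(names(discarded_seqs)))
  edges_d <- pairwise_similarity(discarded_seqs)
  g <- build_ssn(names(discarded_seqs), edges_d, max_evalue, min_identity)
  comp <- ssn_components(g, role = "discarded", case = "upper")
  # cross comparison: one blastp over the union, keep discarded<->accepted
  # pairs passing the same thresholds
  cross <- empty_df(.edge_proto)
  if (length(accepted_seqs)) {
    pool <- c(discarded_seqs, accepted_seqs[!duplicated(names(accepted_seqs))])
    all_edges <- pairwise_similarity(pool)
    is_d_a <- xor(all_edges$seq_a %in% names(discarded_seqs),
                  all_edges$seq_b %in% names(discarded_seqs))
    cross <- all_edges[is_d_a & all_edges$evalue <= max_evalue &
                         all_edges$identity_pct >= min_identity, ,
                       drop = FALSE]
  }
  comp_of <- stats::setNames(comp$cluster, comp$seq_id)
  labels <- sort(unique(comp$cluster))
  # order components as ssn_components did (by their label order)
  comp_order <- unique(comp$cluster[order(match(comp$cluster,
                                                cluster_label(1:10000,
                                                              "upper")))])
  mapped <- character(0)
  fresh_i <- 0L
  final <- stats::setNames(character(length(comp_order)), comp_order)
  for (lab in comp_order) {
    members <- comp$seq_id[comp$cluster == lab]
    sub <- cross[(cross$seq_a %in% members) | (cross$seq_b %in% members), ,
                 drop = FALSE]
    if (nrow(sub)) {
      sub <- sub[order(sub$evalue, -sub$identity_pct), , drop = FALSE]
      acc_id <- ifelse(sub$seq_a[1L] %in% members, sub$seq_b[1L],
                       sub$seq_a[1L])
      acc_cluster <- hit_assign$cluster[match(acc_id, hit_assign$seq_id)]
      final[lab] <- paste0(acc_cluster, "_discarded")
    } else {
      fresh_i <- fresh_i + 1L
      final[lab] <- paste0("X", fresh_i, "_discarded")
    }
  }
  comp$cluster <- unname(final[comp$cluster])
  comp
}
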