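# Independent brute-force oracles. These deliberately re-derive results by
# exhaustive enumeration, sharing no code path with the implementation.

# Enumerate every (strand, frame, start-codon) ORF by walking codon by
# codon from each start-codon occurrence, then apply the one-ORF-per-
# segment priority rule (first ATG, else first TTG, else first GTG).
oracle_orfs <- function(contig, min_len_aa) {
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  stops <- c("TAA", "TAG", "TGA")
  starts <- c("ATG", "TTG", "GTG")
  out <- list()
  for (strand in c("+", "-")) {
    seq <- if (strand == "+") contig else rc(contig)
    L <- nchar(seq)
    cand <- list()
    for (p in seq_len(max(L - 2L, 0L))) {
      codon <- substr(seq, p, p + 2L)
      if (!(codon %in% starts)) next
      q <- p
      repeat {
        if (q + 2L > L) { q <- q - 3L; break }   # last full codon position
        if (substr(seq, q, q + 2L) %in% stops) break
        q <- q + 3L
      }
      if (q < p) next
      has_stop <- substr(seq, q, q + 2L) %in% stops
      aa_len <- (q - p) %/% 3L + ifelse(has_stop, 0L, 1L)
      cand[[length(cand) + 1L]] <- data.frame(
        p = p, e = q + 2L, frame = (p - 1L) %% 3L, codon = codon,
        aa_len = aa_len, stringsAsFactors = FALSE)
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      # group by stop-delimited segment = (frame, segment end)
      for (key in unique(paste(cand$frame, cand$e))) {
        grp <- cand[paste(cand$frame, cand$e) == key, , drop = FALSE]
        pick <- NULL
        for (sc in starts) {
          sub <- grp[grp$codon == sc, , drop = FALSE]
          if (nrow(sub)) { pick <- sub[which.min(sub$p), ]; break }
        }
        if (is.null(pick) || pick$aa_len < min_len_aa) next
        if (strand == "+") {
          s1 <- pick$p; s2 <- pick$e
        } else {
          s1 <- L - pick$e + 1L; s2 <- L - pick$p + 1L
        }
        out[[length(out) + 1L]] <- data.frame(
          strand = strand, start = s1, end = s2, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(strand = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

# Transitive-closure connected components by boolean matrix powering.
oracle_components <- function(nodes, edge_pairs) {
  n <- length(nodes)
  adj <- diag(TRUE, n)
  dimnames(adj) <- list(nodes, nodes)
  if (nrow(edge_pairs)) {
    for (i in seq_len(nrow(edge_pairs))) {
      a <- edge_pairs[i, 1]; b <- edge_pairs[i, 2]
      adj[a, b] <- TRUE; adj[b, a] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  membership <- integer(n)
  names(membership) <- nodes
  comp <- 0L
  for (i in seq_len(n)) {
    if (membership[i] == 0L) {
      comp <- comp + 1L
      membership[adj[i, ] > 0] <- comp
    }
  }
  split(nodes, membership)
}

# Exhaustive re-implementation of the structural filter decision for one
# hit: tests every neighbouring ORF directly against the rule set.
oracle_verdict <- function(hit_row, orfs, req) {
  hlen <- nchar(hit_row$protein)
  if (hlen < req$hit_min_aa || hlen > req$hit_max_aa) return("hit_length")
  nb <- orfs[orfs$genome_id == hit_row$genome_id &
               orfs$contig_id == hit_row$contig_id &
               orfs$strand == hit_row$strand &
               orfs$orf_id != hit_row$orf_id, , drop = FALSE]
  ok_sides <- character(0)
  for (i in seq_len(nrow(nb))) {
    o <- nb[i, ]
    left <- (o$start + o$end) / 2 < (hit_row$start + hit_row$end) / 2
    gap <- if (left) hit_row$start - o$end - 1 else o$start - hit_row$end - 1
    side <- if (hit_row$strand == "+") {
      if (left) "upstream" else "downstream"
    } else {
      if (left) "downstream" else "upstream"
    }
    lmin <- if (side == "upstream") req$partner_min_aa_up else
      req$partner_min_aa_down
    lmax <- if (side == "upstream") req$partner_max_aa_up else
      req$partner_max_aa_down
    plen <- nchar(o$protein)
    if (gap >= -req$max_overlap_bp && gap <= req$max_distance_bp &&
        plen >= lmin && plen <= lmax &&
        !grepl("[NXnx]{8,}", o$nt_seq))
      ok_sides <- union(ok_sides, side)
  }
  accepted <- switch(req$orientation,
                     upstream = "upstream" %in% ok_sides,
                     downstream = "downstream" %in% ok_sides,
                     either = length(ok_sides) >= 1,
                     both = length(ok_sides) == 2)
  if (accepted) "accepted" else "rejected"
}
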