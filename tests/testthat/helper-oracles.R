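# Independent oracles used by the property-based and acceptance tests.

# Exhaustive event oracle: for every node pair, every bipartition of the
# traversing isoform paths is tested literally for mutual edge-exclusivity;
# minimality requires no interior node common to all traversing paths. The
# bundle partition is recovered as the common refinement (meet) of all clean
# bipartitions -- an algorithmic route independent of the package's
# union-find enumeration.
enumerate_events_oracle <- function(graph) {
  paths <- eventscope:::.graph_paths(graph)
  if (length(paths) < 2L) return(list())
  node_paths <- lapply(paths, function(p) {
    e <- graph$edges[match(p, graph$edges$edge_id), , drop = FALSE]
    c(e$from[1L], e$to)
  })
  all_nodes <- sort(unique(unlist(node_paths)))
  events <- list()
  seen <- character(0)
  for (s in all_nodes) {
    for (t in all_nodes[all_nodes > s]) {
      trav <- which(vapply(node_paths, function(np) {
        s %in% np && t %in% np
      }, logical(1)))
      k <- length(trav)
      if (k < 2L) next
      subs <- lapply(trav, function(i) {
        np <- node_paths[[i]]
        paths[[i]][match(s, np):(match(t, np) - 1L)]
      })
      interiors <- lapply(trav, function(i) {
        np <- node_paths[[i]]
        a <- match(s, np); b <- match(t, np)
        if (b - a < 2L) integer(0) else np[(a + 1L):(b - 1L)]
      })
      if (length(Reduce(intersect, interiors))) next
      clean <- list()
      for (mask in seq_len(2L^k - 2L)) {
        if (bitwAnd(mask, 1L) != 1L) next  # fix path 1 in group 1
        g1 <- which(bitwAnd(mask, 2L^(seq_len(k) - 1L)) > 0L)
        g2 <- setdiff(seq_len(k), g1)
        E1 <- unique(unlist(subs[g1]))
        E2 <- unique(unlist(subs[g2]))
        if (!length(intersect(E1, E2))) {
          clean[[length(clean) + 1L]] <- g1
        }
      }
      if (!length(clean)) next
      part <- rep(1L, k)
      for (g1 in clean) {
        part <- as.integer(factor(paste(part, seq_len(k) %in% g1)))
      }
      blocks <- split(seq_len(k), part)
      edge_sets <- lapply(blocks, function(b) sort(unique(unlist(subs[b]))))
      if (length(blocks) == 2L) {
        p1 <- edge_sets[[1L]]; p2 <- edge_sets[[2L]]
        forced_complex <- FALSE
      } else {
        sizes <- vapply(blocks, length, integer(1))
        exlen <- vapply(edge_sets, function(es) {
          e <- graph$edges[match(es, graph$edges$edge_id), , drop = FALSE]
          sum((e$end - e$start)[e$kind == "exonic"])
        }, numeric(1))
        minid <- vapply(edge_sets, function(es) as.numeric(min(es)),
                        numeric(1))
        big <- order(-sizes, -exlen, minid)[1L]
        p1 <- edge_sets[[big]]
        p2 <- sort(unique(unlist(edge_sets[-big])))
        forced_complex <- TRUE
      }
      key <- paste(sort(c(paste(p1, collapse = ","),
                          paste(p2, collapse = ","))), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      events[[length(events) + 1L]] <- list(
        s = s, t = t, path1 = p1, path2 = p2,
        forced_complex = forced_complex
      )
    }
  }
  events
}

event_pair_keys <- function(events) {
  vapply(events, function(ev) {
    paste(sort(c(paste(sort(ev$path1), collapse = ","),
                 paste(sort(ev$path2), collapse = ","))), collapse = "|")
  }, character(1))
}

# 2-D grid search for the penalized NNLS problem. The objective is a convex
# quadratic, so for each grid value of v the minimum over the u grid is
# attained at one of the two grid points bracketing the continuous minimizer;
# grid_nnls exploits this to return exactly the full-grid minimizer in O(grid)
# (grid_nnls_brute evaluates every grid point and is used to validate the
# shortcut on small grids).
grid_nnls <- function(S1, S2, SR, lambda, step = 1e-3, upper = 5) {
  A <- rbind(cbind(S1, S2), c(lambda, -lambda), c(lambda, 0), c(0, lambda))
  b <- c(SR, 0, lambda, lambda)
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, b))
  q <- function(u, v) {
    AtA[1, 1] * u^2 + AtA[2, 2] * v^2 + 2 * AtA[1, 2] * u * v -
      2 * Atb[1] * u - 2 * Atb[2] * v
  }
  v <- seq(0, upper, by = step)
  u_cont <- pmin(pmax((Atb[1] - AtA[1, 2] * v) / AtA[1, 1], 0), upper)
  u_lo <- pmin(pmax(floor(u_cont / step) * step, 0), upper)
  u_hi <- pmin(u_lo + step, upper)
  q_lo <- q(u_lo, v)
  q_hi <- q(u_hi, v)
  u_best <- ifelse(q_lo <= q_hi, u_lo, u_hi)
  q_best <- pmin(q_lo, q_hi)
  i <- which.min(q_best)
  c(u_best[i], v[i])
}

grid_nnls_brute <- function(S1, S2, SR, lambda, step = 1e-3, upper = 5) {
  A <- rbind(cbind(S1, S2), c(lambda, -lambda), c(lambda, 0), c(0, lambda))
  b <- c(SR, 0, lambda, lambda)
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, b))
  u <- seq(0, upper, by = step)
  fu <- AtA[1, 1] * u^2 - 2 * Atb[1] * u
  best <- c(NA_real_, NA_real_)
  bestval <- Inf
  chunk <- 500L
  for (start in seq(1L, length(u), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(u))
    v <- u[idx]
    gv <- AtA[2, 2] * v^2 - 2 * Atb[2] * v
    M <- outer(fu, gv, "+") + 2 * AtA[1, 2] * (u %o% v)
    mi <- which.min(M)
    if (M[mi] < bestval) {
      bestval <- M[mi]
      best <- c(u[(mi - 1L) %% length(u) + 1L],
                v[(mi - 1L) %/% length(u) + 1L])
    }
  }
  best
}

# Per-base membership oracles for interval-set predicates.
interval_bases <- function(x) {
  if (is.null(x) || nrow(x) == 0L) return(integer(0))
  unique(unlist(mapply(function(s, e) seq.int(s, e - 1L), x$start, x$end,
                       SIMPLIFY = FALSE)))
}

subset_oracle <- function(x, y) {
  bx <- interval_bases(x)
  if (!length(bx)) return(TRUE)
  all(bx %in% interval_bases(y))
}

overlap_oracle <- function(x, y) {
  length(intersect(interval_bases(x), interval_bases(y))) > 0L
}

# Literal per-pair evaluation of the two matching expressions.
match_oracle <- function(set1, set2) {
  compat <- function(x, y) subset_oracle(x, y) || subset_oracle(y, x)
  rows <- list()
  for (f1 in set1) {
    for (f2 in set2) {
      if (!identical(f1$chrom, f2$chrom) ||
          !identical(f1$strand, f2$strand)) next
      r_ok <- overlap_oracle(f1$R, f2$R)
      direct <- r_ok && compat(f1$A, f2$A) && compat(f1$B, f2$B)
      swapped <- r_ok && compat(f1$A, f2$B) && compat(f1$B, f2$A)
      if (direct || swapped) {
        rows[[length(rows) + 1L]] <- data.frame(
          event_id_1 = f1$event_id, event_id_2 = f2$event_id,
          rule = if (direct) "direct" else "swapped",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(event_id_1 = character(0), event_id_2 = character(0),
                      rule = character(0)))
  }
  do.call(rbind, rows)
}

random_intervals <- function(n_max = 2L, lo = 0L, hi = 400L) {
  n <- sample(seq_len(n_max), 1L)
  starts <- sort(sample(lo:(hi - 30L), n))
  ends <- starts + sample(5:30, n, replace = TRUE)
  eventscope:::.reduce_intervals(starts, ends)
}

random_footprint <- function(id, chrom = "chr1", strand = "+") {
  list(event_id = id, chrom = chrom, strand = strand,
       A = random_intervals(), B = random_intervals(),
       R = random_intervals())
}

# second-platform variant: shrink intervals (stays contained) and sometimes
# swap the A/B roles
perturb_footprint <- function(fp, id) {
  shrink <- function(df) {
    if (!nrow(df)) return(df)
    w <- df$end - df$start
    d <- pmin(pmax(w %/% 4L, 0L), 5L)
    out <- data.frame(start = df$start + d, end = df$end - d)
    out[out$end > out$start, , drop = FALSE]
  }
  out <- list(event_id = id, chrom = fp$chrom, strand = fp$strand,
              A = shrink(fp$A), B = shrink(fp$B), R = shrink(fp$R))
  if (stats::runif(1) < 0.3) {
    tmp <- out$A; out$A <- out$B; out$B <- tmp
  }
  out
}

random_footprint_sets <- function(n_shared = 4L, n_noise = 3L) {
  set1 <- lapply(seq_len(n_shared + n_noise), function(i) {
    random_footprint(paste0("p1_", i))
  })
  set2 <- c(
    lapply(seq_len(n_shared), function(i) {
      perturb_footprint(set1[[i]], paste0("p2_", i))
    }),
    lapply(seq_len(n_noise), function(i) {
      random_footprint(paste0("p2_n", i))
    })
  )
  list(set1 = set1, set2 = set2)
}
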