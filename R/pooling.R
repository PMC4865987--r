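# Multiplex-PCR pool assignment.
#
# Primer pairs co-amplified in one microfluidic inlet must be mutually
# compatible: products must not overlap or lie within min_gap_bp of each
# other on the same chromosome, product sizes must stay within a tolerance
# of the pool's mean size, and the pool's GC spread must stay within a cap.
# Pool assignment is a deterministic greedy first-fit colouring of the
# conflict graph under those pool-level feasibility checks.

#' Pooling constraint parameters
#'
#' @param min_gap_bp products on the same chromosome closer than this
#'   (strictly) conflict; products separated by exactly `min_gap_bp` are
#'   compatible
#' @param size_tolerance every member's length must be within this fraction
#'   of the pool's mean product length
#' @param gc_span_max maximum max-min product GC within a pool, in
#'   percentage points
#' @param max_pool_size maximum primer pairs per pool
#' @param max_pools maximum number of pools (chip inlets)
#' @param size_rule `"pool"` checks lengths against each pool's own mean
#'   (rechecked on every insertion); `"panel"` checks against the global
#'   mean of all amplicons being pooled
#' @return list of class `pooling_params`
#' @export
pooling_params <- function(min_gap_bp = 5000L, size_tolerance = 0.20,
                           gc_span_max = 15, max_pool_size = 12L,
                           max_pools = 48L, size_rule = c("pool", "panel")) {
  size_rule <- match.arg(size_rule)
  stopifnot(min_gap_bp > 0, size_tolerance > 0, size_tolerance < 1,
            gc_span_max > 0, max_pool_size > 0, max_pools > 0)
  structure(list(min_gap_bp = as.integer(min_gap_bp),
                 size_tolerance = size_tolerance,
                 gc_span_max = gc_span_max,
                 max_pool_size = as.integer(max_pool_size),
                 max_pools = as.integer(max_pools),
                 size_rule = size_rule),
            class = "pooling_params")
}

#' Build the amplicon conflict graph
#'
#' Two amplicons conflict iff they sit on the same chromosome and their
#' product intervals overlap (`OVERLAP`) or are separated by a gap strictly
#' smaller than `min_gap_bp` (`PROXIMITY`). The gap between non-overlapping
#' intervals is `later.start - earlier.end`.
#'
#' @param amplicons amplicon data.frame
#' @param params a [pooling_params()] list
#' @return list of class `conflict_graph` with `nodes` (amplicon ids) and
#'   `edges` (data.frame `a`, `b`, `reason`)
#' @export
build_conflict_graph <- function(amplicons, params = pooling_params()) {
  validate_amplicons(amplicons)
  n <- nrow(amplicons)
  edges <- list()
  # pairwise scan within chromosome, sorted by start
  for (chr in unique(amplicons$chrom)) {
    idx <- which(amplicons$chrom == chr)
    idx <- idx[order(amplicons$start[idx])]
    if (length(idx) < 2) next
    for (i in seq_len(length(idx) - 1L)) {
      for (j in (i + 1L):length(idx)) {
        a <- idx[i]; b <- idx[j]
        gap <- amplicons$start[b] - amplicons$end[a]
        if (gap >= params$min_gap_bp) break  # sorted: later j only farther
        reason <- if (gap < 0) "OVERLAP" else "PROXIMITY"
        edges[[length(edges) + 1L]] <-
          data.frame(a = amplicons$amplicon_id[a],
                     b = amplicons$amplicon_id[b],
                     reason = reason, stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(a = character(0), b = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  structure(list(nodes = amplicons$amplicon_id, edges = edges),
            class = "conflict_graph")
}

# Adjacency list (id -> character vector of conflicting ids).
conflict_adjacency <- function(graph) {
  adj <- setNames(vector("list", length(graph$nodes)), graph$nodes)
  for (k in seq_len(nrow(graph$edges))) {
    a <- graph$edges$a[k]; b <- graph$edges$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

pool_feasible <- function(members, candidate, amplicons, adj, params,
                          panel_mean = NULL) {
  if (length(members) >= params$max_pool_size) return(FALSE)
  if (any(members %in% adj[[candidate]])) return(FALSE)
  all_ids <- c(members, candidate)
  rows <- match(all_ids, amplicons$amplicon_id)
  lens <- amplicons$length[rows]
  mean_len <- if (params$size_rule == "panel") panel_mean else mean(lens)
  if (any(abs(lens - mean_len) > params$size_tolerance * mean_len))
    return(FALSE)
  gcs <- amplicons$gc_fraction[rows]
  if ((max(gcs) - min(gcs)) * 100 > params$gc_span_max) return(FALSE)
  TRUE
}

#' Assign amplicons to multiplex pools
#'
#' Deterministic greedy first-fit: amplicons are ordered by conflict degree
#' (descending), then product length (descending), then amplicon id
#' (ascending), and each is placed into the first existing pool where all
#' pooling invariants still hold, else into a new pool.
#'
#' @param amplicons amplicon data.frame
#' @param graph optional precomputed [build_conflict_graph()] result
#' @param params a [pooling_params()] list
#' @return list of class `pooling_plan` with `pools` (list of character
#'   vectors of amplicon ids), `params`, and `order_policy`
#' @export
assign_pools <- function(amplicons, graph = NULL,
                         params = pooling_params()) {
  validate_amplicons(amplicons)
  if (is.null(graph)) graph <- build_conflict_graph(amplicons, params)
  stopifnot(setequal(graph$nodes, amplicons$amplicon_id))
  adj <- conflict_adjacency(graph)
  degree <- lengths(adj)[amplicons$amplicon_id]
  degree[is.na(degree)] <- 0L
  ord <- order(-degree, -amplicons$length, amplicons$amplicon_id)
  panel_mean <- mean(amplicons$length)
  pools <- list()
  unplaceable <- character(0)
  for (i in ord) {
    id <- amplicons$amplicon_id[i]
    placed <- FALSE
    for (p in seq_along(pools)) {
      if (pool_feasible(pools[[p]], id, amplicons, adj, params, panel_mean)) {
        pools[[p]] <- c(pools[[p]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      if (length(pools) >= params$max_pools) {
        unplaceable <- c(unplaceable, id)
      } else {
        pools[[length(pools) + 1L]] <- id
      }
    }
  }
  if (length(unplaceable))
    stop("pooling infeasible within max_pools; unplaceable amplicons: ",
         paste(unplaceable, collapse = ","), call. = FALSE)
  structure(list(pools = pools, params = params,
                 order_policy = "degree desc, length desc, amplicon_id asc"),
            class = "pooling_plan")
}

#' @export
print.pooling_plan <- function(x, ...) {
  sizes <- lengths(x$pools)
  cat(sprintf("pooling plan: %d amplicons in %d pools (sizes %d-%d)\n",
              sum(sizes), length(sizes), min(sizes), max(sizes)))
  invisible(x)
}

#' Validate a pooling plan against all constraints
#'
#' Re-checks every pooling invariant from scratch: complete single
#' assignment, pool size cap, absence of intra-pool conflict edges,
#' member lengths within tolerance of the pool mean, and GC span.
#'
#' @param plan a `pooling_plan`
#' @param amplicons the amplicon data.frame the plan covers
#' @param params a [pooling_params()] list (defaults to the plan's own)
#' @return data.frame of violations (`pool`, `member`, `constraint`,
#'   `detail`); zero rows iff the plan is valid
#' @export
validate_pooling <- function(plan, amplicons, params = NULL) {
  params <- params %||% plan$params
  validate_amplicons(amplicons)
  assigned <- unlist(plan$pools, use.names = FALSE)
  unknown <- setdiff(assigned, amplicons$amplicon_id)
  if (length(unknown))
    stop("plan references unknown amplicon ids: ",
         paste(unknown, collapse = ","), call. = FALSE)
  v <- list()
  add <- function(pool, member, constraint, detail)
    v[[length(v) + 1L]] <<- data.frame(pool = pool, member = member,
                                       constraint = constraint,
                                       detail = detail,
                                       stringsAsFactors = FALSE)
  dup <- assigned[duplicated(assigned)]
  for (d in unique(dup)) add(NA_integer_, d, "MULTIPLE_ASSIGNMENT",
                             "amplicon appears in more than one pool")
  missing <- setdiff(amplicons$amplicon_id, assigned)
  for (m in missing) add(NA_integer_, m, "UNASSIGNED",
                         "amplicon missing from plan")
  if (length(plan$pools) > params$max_pools)
    add(NA_integer_, NA_character_, "TOO_MANY_POOLS",
        sprintf("%d > %d", length(plan$pools), params$max_pools))
  graph <- build_conflict_graph(amplicons, params)
  edge_key <- paste(pmin(graph$edges$a, graph$edges$b),
                    pmax(graph$edges$a, graph$edges$b))
  panel_mean <- mean(amplicons$length)
  for (p in seq_along(plan$pools)) {
    ids <- plan$pools[[p]]
    if (length(ids) > params$max_pool_size)
      add(p, NA_character_, "POOL_SIZE",
          sprintf("%d > %d", length(ids), params$max_pool_size))
    rows <- match(ids, amplicons$amplicon_id)
    lens <- amplicons$length[rows]
    mean_len <- if (params$size_rule == "panel") panel_mean else mean(lens)
    off <- abs(lens - mean_len) > params$size_tolerance * mean_len
    for (m in ids[off])
      add(p, m, "SIZE_TOLERANCE",
          sprintf("length %d outside %.0f%% of pool mean %.1f",
                  amplicons$length[match(m, amplicons$amplicon_id)],
                  100 * params$size_tolerance, mean_len))
    gcs <- amplicons$gc_fraction[rows]
    if (length(ids) && (max(gcs) - min(gcs)) * 100 > params$gc_span_max)
      add(p, NA_character_, "GC_SPAN",
          sprintf("span %.1f points > %.1f", (max(gcs) - min(gcs)) * 100,
                  params$gc_span_max))
    if (length(ids) > 1) {
      pairs <- utils::combn(sort(ids), 2)
      for (k in seq_len(ncol(pairs))) {
        key <- paste(pairs[1, k], pairs[2, k])
        if (key %in% edge_key) {
          reason <- graph$edges$reason[match(key, edge_key)]
          add(p, paste(pairs[, k], collapse = "+"), reason,
              "conflicting pair pooled together")
        }
      }
    }
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(pool = integer(0), member = character(0),
                  constraint = character(0), detail = character(0),
                  stringsAsFactors = FALSE)
}

#' Write a pooling plan as TSV (pool_id, amplicon_id)
#' @param plan a `pooling_plan`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_pooling_plan <- function(plan, path) {
  df <- data.frame(
    pool_id = rep(seq_along(plan$pools), lengths(plan$pools)),
    amplicon_id = unlist(plan$pools, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
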