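# Lineage recording and phylogeny export.  A lineage table has one row per
# agent ever alive (id, parent, birth, death; parent NA for founders, death
# NA while alive).  For Newick export a parent's branch is subdivided at each
# reproduction into a synthetic fork whose first child is the continuing
# parent and second child the newborn.

#' Create an empty lineage store
#'
#' @param founder_ids Integer ids of the founder agents.
#' @param t0 Birth time stamped on the founders.
#' @return A `lineage_table` data frame with columns `id`, `parent`, `birth`,
#'   `death`.
#' @export
new_lineage <- function(founder_ids, t0 = 0L) {
  lin <- data.frame(id = as.integer(founder_ids), parent = NA_integer_,
                    birth = as.integer(t0), death = NA_integer_)
  class(lin) <- c("lineage_table", "data.frame")
  lin
}

#' Record a birth or a death
#'
#' Append-only lineage bookkeeping.  `record_birth()` adds a child row;
#' `record_death()` stamps the death time of a living agent.  Recording a
#' death twice, a death before birth, or a birth of an existing id is an
#' error.
#'
#' @param lin A `lineage_table`.
#' @param child,parent,id Agent ids.
#' @param t Iteration of the event.
#' @return The updated `lineage_table`.
#' @export
record_birth <- function(lin, child, parent, t) {
  if (child %in% lin$id) stop("agent ", child, " already recorded")
  if (!parent %in% lin$id) stop("unknown parent ", parent)
  pb <- lin$birth[match(parent, lin$id)]
  if (t < pb) stop("child born before its parent")
  out <- rbind(lin, data.frame(id = as.integer(child),
                               parent = as.integer(parent),
                               birth = as.integer(t), death = NA_integer_))
  class(out) <- c("lineage_table", "data.frame")
  out
}

#' @rdname record_birth
#' @export
record_death <- function(lin, id, t) {
  i <- match(id, lin$id)
  if (is.na(i)) stop("unknown agent ", id)
  if (!is.na(lin$death[i])) stop("death of agent ", id, " already recorded")
  if (t < lin$birth[i]) stop("death before birth")
  lin$death[i] <- as.integer(t)
  lin
}

#' Lineage table of a run
#'
#' @param run A `swarm_run`; its lineage table covers every agent alive at
#'   any point of the run.
#' @return The run's `lineage_table`.
#' @export
lineage_from_run <- function(run) run$lineage

#' Rebuild a lineage from an event log
#'
#' Replays birth and death event tables (as found in `run$events`) on top of
#' the founder set; the result is identical to the lineage the run recorded.
#'
#' @param founder_ids Integer founder ids.
#' @param births Data frame with columns `t`, `child`, `parent`.
#' @param deaths Data frame with columns `t`, `id`.
#' @param t0 Founder birth time.
#' @return A `lineage_table`.
#' @export
replay_lineage <- function(founder_ids, births, deaths, t0 = 0L) {
  lin <- new_lineage(founder_ids, t0)
  for (r in seq_len(nrow(births))) {
    lin <- record_birth(lin, births$child[r], births$parent[r], births$t[r])
  }
  for (r in seq_len(nrow(deaths))) {
    lin <- record_death(lin, deaths$id[r], deaths$t[r])
  }
  lin
}

# Newick subtree for one agent from time `from` onward.  children_of maps
# id -> integer vector of child ids in birth order; at each fork the
# continuing parent precedes the newborn.
newick_node <- function(id, from, lin, children_of, t_end) {
  i <- match(id, lin$id)
  end <- if (is.na(lin$death[i])) t_end else lin$death[i]
  kids <- children_of[[as.character(id)]]
  if (!is.null(kids)) {
    kb <- lin$birth[match(kids, lin$id)]
    sel <- kb >= from & kb <= t_end
    kids <- kids[sel]; kb <- kb[sel]
  }
  if (is.null(kids) || length(kids) == 0L) {
    return(sprintf("a%d:%s", id, format(end - from, scientific = FALSE)))
  }
  ct <- kb[1]
  rest <- newick_node(id, ct, lin, prune_first_child(children_of, id), t_end)
  child <- newick_node(kids[1], ct, lin, children_of, t_end)
  sprintf("(%s,%s):%s", rest, child, format(ct - from, scientific = FALSE))
}

prune_first_child <- function(children_of, id) {
  key <- as.character(id)
  children_of[[key]] <- children_of[[key]][-1L]
  children_of
}

#' Export a lineage as Newick text
#'
#' Each founder yields one rooted tree; a parent's branch is subdivided at
#' each reproduction event, the continuing parent forking first and the
#' newborn second.  Branch lengths are iterations; leaves are labelled
#' `a<id>`; open branches are cut at `t_end`.
#'
#' @param lin A `lineage_table`.
#' @param t_end Iteration at which living branches are truncated.
#' @param pseudo_root If `TRUE`, the founder trees are attached to a single
#'   zero-height pseudo-root and a single statement is returned; otherwise
#'   one Newick statement per founder.
#' @param file Optional path; if given, the statements are written there
#'   (one per line).
#' @return Character vector of Newick statements (invisibly if `file` is
#'   given).
#' @examples
#' lin <- new_lineage(1)
#' lin <- record_birth(lin, 2, 1, 50)
#' export_newick(lin, t_end = 100)  # "((a1:50,a2:50):50);" shape
#' @export
export_newick <- function(lin, t_end, pseudo_root = FALSE, file = NULL) {
  stopifnot(inherits(lin, "lineage_table"))
  founders <- lin$id[is.na(lin$parent)]
  kids <- split(lin$id[!is.na(lin$parent)], lin$parent[!is.na(lin$parent)])
  kids <- lapply(kids, function(v) {
    v[order(lin$birth[match(v, lin$id)], v)]
  })
  subtrees <- vapply(founders, function(f) {
    newick_node(f, lin$birth[match(f, lin$id)], lin, kids, t_end)
  }, character(1))
  out <- if (pseudo_root && length(subtrees) > 1L) {
    sprintf("(%s):0;", paste(subtrees, collapse = ","))
  } else {
    paste0(subtrees, ";")
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Birth (fork) rate over time
#'
#' Histogram of reproduction events in fixed-width time bins, the "fork
#' burst" profile plotted against the swarming order parameter.
#'
#' @param lin A `lineage_table`.
#' @param bin_width Bin width in iterations.
#' @param t_end Last iteration covered (defaults to the latest event).
#' @return Data frame with `t` (bin start) and `births`.
#' @export
fork_rate_series <- function(lin, bin_width = 1000, t_end = NULL) {
  births <- lin$birth[!is.na(lin$parent)]
  if (is.null(t_end)) {
    t_end <- max(c(births, lin$death, 0), na.rm = TRUE)
  }
  breaks <- seq(0, ceiling(t_end / bin_width) * bin_width, by = bin_width)
  if (length(breaks) < 2L) breaks <- c(0, bin_width)
  counts <- if (length(births)) {
    tabulate(findInterval(births, breaks, left.open = TRUE),
             nbins = length(breaks) - 1L)
  } else {
    integer(length(breaks) - 1L)
  }
  data.frame(t = breaks[-length(breaks)], births = counts)
}
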