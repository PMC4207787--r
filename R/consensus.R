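# Per-engine docking score tables, best-first ranking, top-N truncation with
# boundary-tie handling, per-conformation rank intersection and pooling.

#' Construct a docking score table
#'
#' @param ids compound identifiers (unique within the table).
#' @param scores finite numeric scores.
#' @param engine engine label (e.g. `"engineA"`).
#' @param conformation receptor conformation label.
#' @param direction `"higher"` if larger scores are better (positive
#'   scoring-function scales), `"lower"` if more negative is better
#'   (energy-like scales).
#' @return object of class `ScoreTable`.
#' @export
score_table <- function(ids, scores, engine, conformation,
                        direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  ids <- as.character(ids)
  if (length(ids) == 0) stop("empty score table")
  if (length(ids) != length(scores)) stop("ids and scores lengths differ")
  if (anyDuplicated(ids)) stop("duplicate compound ids in score table")
  if (any(!is.finite(scores))) stop("non-finite score for compound ",
                                    ids[which(!is.finite(scores))[1]])
  structure(list(engine = engine, conformation = conformation,
                 entries = data.frame(id = ids, score = scores,
                                      stringsAsFactors = FALSE),
                 direction = direction),
            class = "ScoreTable")
}

#' @export
print.ScoreTable <- function(x, ...) {
  cat("<ScoreTable>", x$engine, "/", x$conformation, ":",
      nrow(x$entries), "compounds,", x$direction, "is better\n")
  invisible(x)
}

#' Read a score table from a two-column delimited file
#' @param path CSV with columns `compound_id`, `score`.
#' @param engine,conformation,direction table metadata (see [score_table()]).
#' @return a `ScoreTable`.
#' @export
read_score_table <- function(path, engine, conformation,
                             direction = c("higher", "lower")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "score") %in% names(df)))
    stop("score file needs columns compound_id, score: ", path)
  score_table(df$compound_id, df$score, engine, conformation,
              match.arg(direction))
}

#' Rank a score table best-first
#'
#' Ties are broken by lexicographic compound id so the ordering is
#' deterministic.
#'
#' @param table a `ScoreTable`.
#' @return character vector of compound ids, best first.
#' @export
rank_compounds <- function(table) {
  stopifnot(inherits(table, "ScoreTable"))
  e <- table$entries
  key <- if (table$direction == "higher") -e$score else e$score
  e$id[order(key, e$id)]
}

#' Top-N compounds of a score table
#'
#' Returns the ids of the best `n` compounds. If the score at the boundary
#' is tied with compounds beyond it, all boundary-tied compounds are
#' included (the set may exceed `n`; a warning reports the excess).
#'
#' @param table a `ScoreTable`.
#' @param n list size (default 2000).
#' @return character vector of ids.
#' @export
top_n <- function(table, n = 2000) {
  stopifnot(inherits(table, "ScoreTable"))
  if (n <= 0) stop("n must be positive")
  e <- table$entries
  key <- if (table$direction == "higher") -e$score else e$score
  ord <- order(key, e$id)
  if (n >= nrow(e)) return(e$id[ord])
  boundary <- key[ord][n]
  keep <- which(key[ord] <= boundary)
  if (length(keep) > n)
    warning("boundary tie at rank ", n, ": returning ", length(keep),
            " compounds")
  e$id[ord][keep]
}

#' Consensus (intersection) of two engines' top lists
#'
#' @param ids_a,ids_b top-N id sets from two different engines on the same
#'   conformation.
#' @param engine_a,engine_b engine labels; equal labels are a misuse error
#'   (consensus requires independent engines).
#' @param conformation conformation label carried into the result.
#' @return list with `conformation`, `ids` (the intersection), `n_a`, `n_b`.
#' @export
consensus <- function(ids_a, ids_b, engine_a = "engineA",
                      engine_b = "engineB", conformation = "") {
  if (identical(engine_a, engine_b))
    stop("consensus requires two different engines, got '", engine_a,
         "' twice")
  common <- intersect(ids_a, ids_b)
  list(conformation = conformation, ids = sort(common),
       n_a = length(ids_a), n_b = length(ids_b))
}

#' Per-conformation consensus of two score tables
#'
#' Ranks both tables, takes the top `n` of each and intersects. The two
#' tables must score the same compound universe; mismatched universes are
#' an error rather than a silent bias.
#'
#' @param table_a,table_b `ScoreTable`s from different engines, same
#'   conformation.
#' @param n top-list size per engine (default 2000).
#' @return as [consensus()].
#' @export
consensus_pair <- function(table_a, table_b, n = 2000) {
  stopifnot(inherits(table_a, "ScoreTable"), inherits(table_b, "ScoreTable"))
  if (!identical(table_a$conformation, table_b$conformation))
    stop("tables come from different conformations ('",
         table_a$conformation, "' vs '", table_b$conformation, "')")
  if (!setequal(table_a$entries$id, table_b$entries$id))
    stop("engines scored different compound universes for conformation '",
         table_a$conformation, "'")
  consensus(top_n(table_a, n), top_n(table_b, n),
            engine_a = table_a$engine, engine_b = table_b$engine,
            conformation = table_a$conformation)
}

#' Pool per-conformation consensus sets
#'
#' Builds the union of the per-conformation intersections with provenance
#' (which conformations retained each compound). Because a compound can be
#' retained by several conformations, the sum of the per-conformation
#' counts and the size of the union can differ; both statistics are always
#' reported rather than silently picking one reading.
#'
#' @param results list of per-conformation consensus results (from
#'   [consensus_pair()] or [consensus()]).
#' @return object of class `ConsensusResult`: `per_conformation` (named
#'   counts), `sum_of_counts`, `union_size`, `pooled` (data.frame `id`,
#'   `conformations`, `n_conformations`).
#' @export
pool_conformations <- function(results) {
  if (length(results) == 0) stop("no per-conformation results to pool")
  confs <- vapply(results, function(r) as.character(r$conformation),
                  character(1))
  counts <- vapply(results, function(r) length(r$ids), integer(1))
  names(counts) <- confs
  ids_all <- unlist(lapply(results, function(r) r$ids), use.names = FALSE)
  prov <- rep(confs, times = counts)
  pooled <- stats::aggregate(list(conformations = prov),
                             by = list(id = ids_all),
                             FUN = function(v) paste(v, collapse = ","))
  pooled$n_conformations <- lengths(strsplit(pooled$conformations, ","))
  pooled <- pooled[order(pooled$id), ]
  rownames(pooled) <- NULL
  structure(list(per_conformation = counts,
                 sum_of_counts = sum(counts),
                 union_size = nrow(pooled),
                 pooled = pooled),
            class = "ConsensusResult")
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat("<ConsensusResult>\n")
  for (nm in names(x$per_conformation))
    cat("  ", nm, ":", x$per_conformation[[nm]], "common compounds\n")
  cat("  sum of counts:", x$sum_of_counts,
      " | union:", x$union_size, "\n")
  invisible(x)
}
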