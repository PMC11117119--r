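#' Select the top (or bottom) fraction of nodes by a metric
#'
#' Returns the `ceiling(fraction * N)` nodes with the largest (or smallest)
#' metric values. Ties are broken deterministically by node index.
#'
#' @param values Numeric metric vector (one value per node).
#' @param fraction Fraction of nodes to select, in `(0, 1]` (default 0.1).
#' @param direction `"highest"` or `"lowest"`.
#' @return Integer vector of selected node indices.
#' @examples
#' top_fraction(c(3, 1, 2), fraction = 1 / 3)  # node 1
#' @export
top_fraction <- function(values, fraction = 0.1,
                         direction = c("highest", "lowest")) {
  direction <- match.arg(direction)
  if (length(values) == 0) stop("`values` is empty")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must lie in (0, 1]")
  k <- ceiling(fraction * length(values))
  # tie-break by node index regardless of direction
  ord <- if (direction == "highest")
    order(-values, seq_along(values)) else order(values, seq_along(values))
  sort(ord[seq_len(k)])
}

#' Classify influencers and followers
#'
#' Influencers are the top `fraction` of nodes by net influence, followers
#' the bottom `fraction`. Selected nodes whose influence sign is
#' inconsistent with the class (a "top" node with negative influence, or a
#' "bottom" node with positive influence) are flagged rather than silently
#' included, since the labels equate the extremes with positive/negative
#' net influence.
#'
#' @param influence Net influence vector (from [net_influence()]).
#' @param fraction Fraction per class (default 0.1).
#' @return List with integer vectors `influencers`, `followers` and the
#'   flagged subsets `influencers_flagged`, `followers_flagged`.
#' @export
influencer_followers <- function(influence, fraction = 0.1) {
  top <- top_fraction(influence, fraction, "highest")
  bottom <- top_fraction(influence, fraction, "lowest")
  list(influencers = top,
       followers = bottom,
       influencers_flagged = top[influence[top] <= 0],
       followers_flagged = bottom[influence[bottom] >= 0])
}

#' Distribution of a node set across resting-state networks
#'
#' Counts and proportions (of the selected set) per RSN, e.g. where the top
#' 10% influencer nodes live. Networks absent from the set report zero.
#'
#' @param node_set Node indices or node ids.
#' @param partition An `rsn_partition` (named label vector).
#' @return Data frame with columns `rsn`, `count`, `proportion`
#'   (proportions sum to 1).
#' @export
rsn_distribution <- function(node_set, partition) {
  partition <- as_rsn_partition(partition)
  if (length(node_set) == 0)
    stop("`node_set` is empty; the distribution is undefined")
  ids <- if (is.numeric(node_set)) {
    if (any(node_set < 1 | node_set > length(partition)))
      stop("node index out of range of the partition")
    names(partition)[node_set]
  } else as.character(node_set)
  unknown <- setdiff(ids, names(partition))
  if (length(unknown))
    stop("node(s) not in partition: ", paste(unknown, collapse = ", "))
  counts <- table(factor(partition[ids], levels = rsn_label_set()))
  data.frame(rsn = rsn_label_set(), count = as.integer(counts),
             proportion = as.numeric(counts) / length(ids),
             stringsAsFactors = FALSE)
}

#' Node-level metric table
#'
#' One row per node with its strength, net influence, flow, and RSN label —
#' the joint quantities behind strength-profile and network-level summaries.
#'
#' @param analysis A [perturb_analysis()] result (or a data frame with
#'   columns `node_id`, `strength`, `net_influence`, `flow`).
#' @param partition An `rsn_partition` covering all nodes.
#' @return Data frame with columns `node_id`, `strength`, `net_influence`,
#'   `flow`, `rsn`.
#' @export
metric_table <- function(analysis, partition) {
  df <- if (inherits(analysis, "perturbation_analysis"))
    as.data.frame(analysis) else as.data.frame(analysis)
  need <- c("node_id", "strength", "net_influence", "flow")
  if (!all(need %in% names(df)))
    stop("analysis table must have columns ", paste(need, collapse = ", "))
  partition <- as_rsn_partition(partition, node_ids = df$node_id)
  df$rsn <- unname(partition[df$node_id])
  df
}

#' Per-network averages of net influence and flow
#'
#' Sums each metric over the member nodes of every RSN and divides by the
#' member count ("per node" values). Because net influence is conserved
#' (sums to zero over the whole network), the count-weighted per-node
#' influences recombine to zero. Networks with no member nodes are reported
#' with `NA` metrics, not zero. Optionally adds counts of top-fraction
#' influencer / follower / high-flow membership per network.
#'
#' @param table A [metric_table()].
#' @param fraction Top fraction used for the membership counts (default 0.1).
#' @return Data frame (class `rsn_summary`) with columns `rsn`, `n_nodes`,
#'   `influence_per_node`, `flow_per_node`, `n_influencers`, `n_followers`,
#'   `n_top_flow`.
#' @export
rsn_summary <- function(table, fraction = 0.1) {
  stopifnot(all(c("rsn", "net_influence", "flow") %in% names(table)))
  lv <- rsn_label_set()
  rsn <- factor(table$rsn, levels = lv)
  counts <- as.integer(table(rsn))
  sum_by <- function(v) as.numeric(tapply(v, rsn, sum, default = NA_real_))
  cls <- influencer_followers(table$net_influence, fraction)
  top_flow <- top_fraction(table$flow, fraction, "highest")
  count_in <- function(idx) as.integer(table(factor(table$rsn[idx], levels = lv)))
  out <- data.frame(rsn = lv, n_nodes = counts,
                    influence_per_node = sum_by(table$net_influence) / counts,
                    flow_per_node = sum_by(table$flow) / counts,
                    n_influencers = count_in(cls$influencers),
                    n_followers = count_in(cls$followers),
                    n_top_flow = count_in(top_flow),
                    stringsAsFactors = FALSE)
  out$influence_per_node[counts == 0] <- NA_real_
  out$flow_per_node[counts == 0] <- NA_real_
  class(out) <- c("rsn_summary", "data.frame")
  out
}

#' Relationship between a node metric and node strength
#'
#' Spearman rank correlation between the metric and node strength, plus a
#' strength-binned mean profile. Bins are strength quantiles so heavy-tailed
#' strength distributions do not produce empty bins.
#'
#' @param table A [metric_table()] (or any data frame with `strength` and
#'   the metric column); needs at least 5 nodes.
#' @param metric `"net_influence"` or `"flow"`.
#' @param bins Number of quantile bins (default 10).
#' @return List with `rho` (Spearman correlation, `NA` with an explanatory
#'   `note` if strength is constant) and `profile` (data frame: bin,
#'   mean strength, mean metric, node count).
#' @export
strength_relationship <- function(table, metric = c("net_influence", "flow"),
                                  bins = 10) {
  metric <- match.arg(metric)
  stopifnot(all(c("strength", metric) %in% names(table)))
  s <- table$strength
  v <- table[[metric]]
  if (length(s) < 5) stop("need at least 5 nodes")
  if (max(s) == min(s)) {
    return(list(rho = NA_real_,
                note = "strength is constant; rank correlation undefined",
                profile = NULL))
  }
  rho <- stats::cor(s, v, method = "spearman")
  probs <- seq(0, 1, length.out = bins + 1)
  brk <- unique(quantile(s, probs, names = FALSE))
  bin <- cut(s, brk, include.lowest = TRUE, labels = FALSE)
  profile <- data.frame(
    bin = sort(unique(bin)),
    strength = as.numeric(tapply(s, bin, mean)),
    metric = as.numeric(tapply(v, bin, mean)),
    n = as.integer(table(bin)))
  names(profile)[3] <- metric
  list(rho = rho, profile = profile)
}
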