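#' Simulate a time-scaled birth-death tree
#'
#' Forward (crown-conditioned) constant-rate birth-death simulation,
#' stopped the first time the number of extant lineages reaches `n_tips`
#' and extended by one additional exponential waiting time so tip branches
#' do not end exactly at a speciation event. Extinct lineages are pruned,
#' so the returned tree is ultrametric with exactly `n_tips` tips.
#' Replicates that go fully extinct are retried up to `max_retries` times.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param birth speciation rate (events/Ma), must exceed `death`.
#' @param death extinction rate (events/Ma), >= 0.
#' @param seed integer seed; identical seeds give identical trees.
#' @param max_retries number of fresh attempts before giving up when
#'   lineages go extinct.
#' @return an ultrametric `phylo` with tips labelled `t1..tN`.
#' @examples
#' phy <- simulate_tree(10, birth = 1, death = 0.3, seed = 1)
#' ape::is.ultrametric(phy)
#' @export
simulate_tree <- function(n_tips, birth, death = 0, seed = NULL,
                          max_retries = 1000L) {
  stopifnot(n_tips >= 2, birth > death, death >= 0)
  with_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      phy <- sim_bd_once(n_tips, birth, death)
      if (!is.null(phy)) return(phy)
    }
    stop(sprintf(
      "birth-death simulation went extinct in all %d attempts (retry cap)",
      max_retries))
  })
}

# One crown-conditioned forward pass; NULL on total extinction.
sim_bd_once <- function(n_tips, birth, death) {
  parent <- c(0L, 0L)          # lineage index of parent (0 = crown root)
  t_birth <- c(0, 0)
  t_end <- c(NA_real_, NA_real_)
  status <- c("alive", "alive")
  t <- 0
  total <- birth + death
  repeat {
    alive <- which(status == "alive")
    k <- length(alive)
    if (k == 0L) return(NULL)
    if (k == n_tips) break
    t <- t + rexp(1L, k * total)
    i <- alive[sample.int(k, 1L)]
    t_end[i] <- t
    if (runif(1L) < birth / total) {
      status[i] <- "internal"
      parent <- c(parent, i, i)
      t_birth <- c(t_birth, t, t)
      t_end <- c(t_end, NA_real_, NA_real_)
      status <- c(status, "alive", "alive")
    } else {
      status[i] <- "extinct"
    }
  }
  t_stop <- t + rexp(1L, n_tips * total)
  alive <- status == "alive"
  t_end[alive] <- t_stop
  status[alive] <- "extant"

  # lineages are edges; speciating lineages end at internal nodes
  is_tip <- status %in% c("extant", "extinct")
  n_tip_all <- sum(is_tip)
  tip_id <- integer(length(parent))
  tip_id[is_tip] <- seq_len(n_tip_all)
  node_id <- integer(length(parent))          # node at the lineage's end
  node_id[!is_tip] <- n_tip_all + 1L + seq_len(sum(!is_tip))
  end_node <- ifelse(is_tip, tip_id, node_id)
  from_node <- integer(length(parent))
  from_node[parent == 0L] <- n_tip_all + 1L
  from_node[parent > 0L] <- node_id[parent[parent > 0L]]

  labels <- character(n_tip_all)
  labels[tip_id[status == "extant"]] <- paste0("t", seq_len(n_tips))
  labels[tip_id[status == "extinct"]] <-
    paste0("x", seq_len(sum(status == "extinct")))

  phy <- structure(list(
    edge = cbind(from_node, end_node),
    edge.length = t_end - t_birth,
    tip.label = labels,
    Nnode = sum(!is_tip) + 1L
  ), class = "phylo")
  storage.mode(phy$edge) <- "integer"
  phy <- ape::reorder.phylo(phy, "cladewise")

  if (any(status == "extinct")) {
    phy <- ape::drop.tip(phy, labels[tip_id[status == "extinct"]],
                         collapse.singles = TRUE)
    if (is.null(phy) || ape::Ntip(phy) != n_tips) return(NULL)
    phy$root.edge <- NULL
  }
  check_tree(phy)
}
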