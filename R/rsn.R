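#' Resting-state-network masks over brain areas
#'
#' Each of the eight canonical resting-state networks (default mode, visual,
#' auditory-phonological, somatomotor, memory, ventral stream, dorsal
#' attention, working memory) is described by a three-level ordinal mask over
#' the functional areas: `none`, `medium`, or `high` contribution, coded
#' 0 / 1 / 2 and normalized to a unit-sum weight vector (the Bhattacharyya
#' coefficient compares distributions on the area simplex).
#'
#' @param name network name.
#' @param levels character vector over functional areas
#'   (`"none"|"medium"|"high"`), named or ordered by area id.
#' @param area_ids integer area ids the mask is defined over.
#' @return An object of class `rsn_mask` with fields `name`, `levels`,
#'   `area_ids`, `weights` (unit-sum numeric vector).
#' @export
rsn_mask <- function(name, levels, area_ids) {
  lv <- match(levels, c("none", "medium", "high")) - 1L
  if (anyNA(lv)) stop("levels must be none/medium/high", call. = FALSE)
  if (length(lv) != length(area_ids))
    stop("one level per area required", call. = FALSE)
  if (all(lv == 0)) stop("mask needs at least one non-none area", call. = FALSE)
  w <- lv / sum(lv)
  structure(list(name = name, levels = levels, area_ids = as.integer(area_ids),
                 weights = w),
            class = "rsn_mask")
}

#' The eight canonical resting-state network names
#' @export
rsn_names <- function() {
  c("default mode", "visual", "auditory-phonological", "somatomotor",
    "memory", "ventral stream", "dorsal attention", "working memory")
}

#' Generate synthetic resting-state-network masks
#'
#' Stand-in for empirical resting-state cartography: each of the eight
#' networks marks a random subset of the functional cortical areas
#' (`n_high` emphasized, `n_medium` mentioned).  Purely synthetic; used to
#' exercise the matching machinery on generated brains.
#'
#' @param parc a [parcellation()].
#' @param seed integer RNG seed.
#' @param n_medium,n_high areas per level and network.
#' @return named list of [rsn_mask()] objects.
#' @export
generate_rsn_masks <- function(parc, seed = 1L, n_medium = 3L, n_high = 2L) {
  set.seed(seed)
  fun <- functional_areas(parc)
  cort <- parc$areas$id[parc$areas$kind == "cortical" & !parc$areas$is_callosal]
  masks <- lapply(rsn_names(), function(nm) {
    pick <- sample(cort, n_medium + n_high)
    lv <- rep("none", length(fun))
    lv[match(pick[seq_len(n_high)], fun)] <- "high"
    lv[match(pick[n_high + seq_len(n_medium)], fun)] <- "medium"
    rsn_mask(nm, lv, fun)
  })
  names(masks) <- rsn_names()
  masks
}

#' Read / write resting-state-network masks as TSV
#'
#' Columns: `area_label`, `network_name`, `level` (`none|medium|high`); areas
#' absent for a network default to `none`.
#'
#' @param path TSV file.
#' @param parc a [parcellation()] (defines labels and the area universe).
#' @return `read_rsn_masks`: named list of [rsn_mask()].
#' @export
read_rsn_masks <- function(path, parc) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  fun <- functional_areas(parc)
  labels <- parc$areas$name[match(fun, parc$areas$id)]
  out <- lapply(split(df, df$network_name), function(d) {
    lv <- rep("none", length(fun))
    idx <- match(d$area_label, labels)
    if (anyNA(idx)) stop("unknown area label in mask file", call. = FALSE)
    lv[idx] <- d$level
    rsn_mask(d$network_name[1], lv, fun)
  })
  out[order(match(names(out), rsn_names()))]
}

#' @rdname read_rsn_masks
#' @param masks named list of [rsn_mask()].
#' @export
write_rsn_masks <- function(masks, path, parc) {
  labels <- parc$areas$name[match(functional_areas(parc), parc$areas$id)]
  rows <- do.call(rbind, lapply(masks, function(m) {
    keep <- m$levels != "none"
    data.frame(area_label = labels[keep], network_name = m$name,
               level = m$levels[keep])
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Coarse-grain a node eigenvector to area weights
#'
#' Squared (or absolute) eigenvector elements are summed within each
#' functional area and the result is normalized to unit sum, turning the
#' node-level pattern into a distribution over areas comparable to a mask.
#'
#' @param v numeric node vector (unit length).
#' @param parc a [parcellation()].
#' @param metric `"square"` or `"absolute"`.
#' @return named numeric vector over functional areas, summing to 1.
#' @export
coarse_grain <- function(v, parc, metric = c("square", "absolute")) {
  metric <- match.arg(metric)
  na <- node_areas(parc)
  if (length(v) != length(na))
    stop("eigenvector length does not match the node set", call. = FALSE)
  x <- if (metric == "square") v^2 else abs(v)
  agg <- rowsum(x, group = na, reorder = TRUE)
  out <- numeric(n_areas(parc))
  out[as.integer(rownames(agg))] <- agg
  fun <- functional_areas(parc)
  w <- out[fun]
  s <- sum(w)
  if (s > 0) w <- w / s
  names(w) <- as.character(fun)
  w
}

#' Candidate area patterns of one eigenspace
#'
#' The coarse-grained single eigenvectors plus the renormalized sums of all
#' their multi-vector combinations: for three eigenvectors the seven
#' candidates EV1, EV2, EV3, EV1+2, EV1+3, EV2+3, EV1+2+3; for two, three
#' candidates; for one, a single candidate.
#'
#' @param eig an [decompose_response()] eigenspace.
#' @param parc a [parcellation()].
#' @param metric coarse-graining metric, see [coarse_grain()].
#' @return named list of unit-sum area weight vectors; names are the
#'   combination ids.
#' @export
candidate_patterns <- function(eig, parc, metric = "square") {
  k <- ncol(eig$vectors)
  singles <- lapply(seq_len(k), function(j)
    coarse_grain(eig$vectors[, j], parc, metric))
  combos <- list()
  if (k >= 2) {
    for (sz in 2:k) {
      for (idx in utils::combn(k, sz, simplify = FALSE)) {
        w <- Reduce(`+`, singles[idx])
        combos[[paste0("EV", paste(idx, collapse = "+"))]] <- w / sum(w)
      }
    }
  }
  names(singles) <- paste0("EV", seq_len(k))
  c(singles, combos)
}

#' Bhattacharyya coefficient between two area weight distributions
#'
#' `BC = sum_i sqrt(p_i q_i)`, the overlap of two unit-sum non-negative
#' vectors: 1 when identical, 0 when their supports are disjoint.
#'
#' @param p,q non-negative numeric vectors summing to 1.
#' @return overlap in `[0, 1]`.
#' @export
bhattacharyya_coefficient <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch", call. = FALSE)
  if (any(p < 0) || any(q < 0)) stop("negative entries", call. = FALSE)
  sum(sqrt(p * q))
}

#' Permutation test of a candidate pattern against a mask
#'
#' The mask's area weights are permuted `N` times (without replacement), the
#' Bhattacharyya coefficient is recomputed for each permutation, and the
#' p value is `(n + 1) / (N + 1)` with `n` the count of permuted
#' coefficients strictly greater than the observed one.
#'
#' @param candidate unit-sum area weight vector.
#' @param mask an [rsn_mask()] (or unit-sum weight vector).
#' @param N number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @return An object of class `match_result`: `BC`, `n_exceed`, `N_perm`,
#'   `p` (and `p_corrected`/`significant` once [holm_correct()] has been
#'   applied over the comparison family).
#' @export
permutation_test <- function(candidate, mask, N = 10000L, seed = 1L) {
  q <- if (inherits(mask, "rsn_mask")) mask$weights else mask
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  bc <- bhattacharyya_coefficient(candidate, q)
  set.seed(seed)
  sq_p <- sqrt(candidate)
  sq_q <- sqrt(q)
  n_exceed <- 0L
  # chunked to bound memory at large N
  chunk <- 20000L
  left <- as.integer(N)
  while (left > 0) {
    m <- min(chunk, left)
    P <- vapply(seq_len(m), function(i) sample(sq_q), numeric(length(q)))
    bch <- colSums(sq_p * P)
    n_exceed <- n_exceed + sum(bch > bc)
    left <- left - m
  }
  structure(list(BC = bc, n_exceed = n_exceed, N_perm = as.integer(N),
                 p = (n_exceed + 1) / (N + 1),
                 p_corrected = NA_real_, significant = NA),
            class = "match_result")
}

#' Bonferroni-Holm step-down correction
#'
#' Standard Holm adjustment with monotonicity enforcement over a family of
#' `m` comparisons (at least as many as there are p values; unobserved
#' family members count as tests).
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @param m family size (default: `length(p)`).
#' @return corrected p values, capped at 1.
#' @export
holm_correct <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("p values must be in [0, 1]", call. = FALSE)
  if (m < length(p)) stop("family size smaller than the p values", call. = FALSE)
  o <- order(p)
  adj <- pmin(1, (m - seq_along(p) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(length(p))
  out[o] <- adj
  out
}

#' Match all candidate patterns of an eigenspace against RSN masks
#'
#' Computes the Bhattacharyya coefficient and permutation p value for every
#' (candidate, mask) pair, then applies the Bonferroni-Holm correction over
#' the whole family (by default `#masks * #candidates` comparisons; pass
#' `m_comparisons = 24` for the fixed historical family of eight networks
#' times three eigenvectors).
#'
#' @param eig an eigenspace.
#' @param masks named list of [rsn_mask()].
#' @param parc a [parcellation()].
#' @param metric coarse-graining metric.
#' @param N permutations per comparison.
#' @param seed integer RNG seed.
#' @param m_comparisons family size for Holm (default `NULL`: all pairs).
#' @param alpha_sig significance level (default 0.05).
#' @return data.frame with one row per (candidate, mask): `site`, `alpha`,
#'   `sigma`, `metric`, `candidate`, `rsn`, `BC`, `p`, `p_corrected`,
#'   `significant`.
#' @export
match_rsn <- function(eig, masks, parc, metric = "square", N = 10000L,
                      seed = 1L, m_comparisons = NULL, alpha_sig = 0.05) {
  cands <- candidate_patterns(eig, parc, metric)
  rows <- list()
  i <- 0L
  for (ci in seq_along(cands)) {
    for (mi in seq_along(masks)) {
      i <- i + 1L
      mr <- permutation_test(cands[[ci]], masks[[mi]], N = N,
                             seed = seed + i)
      rows[[i]] <- data.frame(
        site = eig$condition$site, alpha = eig$condition$alpha,
        sigma = eig$condition$sigma, metric = metric,
        candidate = names(cands)[ci], rsn = masks[[mi]]$name,
        BC = mr$BC, p = mr$p, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  m <- if (is.null(m_comparisons)) nrow(df) else m_comparisons
  df$p_corrected <- holm_correct(df$p, m = m)
  df$significant <- df$p_corrected < alpha_sig
  df
}

#' Graph metrics of the heterogeneous SC
#'
#' Seven per-area measures of the directed weighted area graph: in-, out-
#' and total degree (tie counts), in-, out- and total strength (weight
#' sums), and the weighted directed clustering coefficient (Fagiolo's
#' generalization: cube of the cube-root weight matrix symmetrized over
#' directions, normalized by the possible directed triangles
#' `d_tot (d_tot - 1) - 2 d_bidir`).
#'
#' @param het a [heterogeneous_sc()].
#' @return data.frame (areas x 7): `in_degree`, `out_degree`, `total_degree`,
#'   `in_strength`, `out_strength`, `total_strength`, `clustering`.
#' @export
graph_metrics <- function(het) {
  W <- het$weights           # W[i, j] = weight of j -> i
  A <- (W > 0) * 1
  in_deg <- rowSums(A)
  out_deg <- colSums(A)
  in_str <- rowSums(W)
  out_str <- colSums(W)
  # Fagiolo clustering on the j -> i convention: work with the transposed
  # (source-row) adjacency so formulas read as in the directed-graph literature
  At <- t(A)
  Wt <- t(W)
  mx <- max(Wt)
  Wh <- if (mx > 0) (Wt / mx)^(1 / 3) else Wt
  Ssym <- Wh + t(Wh)
  num <- diag(Ssym %*% Ssym %*% Ssym) / 2
  d_tot <- in_deg + out_deg
  d_bi <- diag(At %*% At)
  den <- d_tot * (d_tot - 1) - 2 * d_bi
  clustering <- ifelse(den > 0, num / den, 0)
  data.frame(in_degree = in_deg, out_degree = out_deg,
             total_degree = in_deg + out_deg,
             in_strength = in_str, out_strength = out_str,
             total_strength = in_str + out_str,
             clustering = clustering)
}

#' Compare a candidate pattern with the connectivity structure
#'
#' Each of the seven graph metrics (restricted to the functional areas and
#' normalized to unit sum) is compared with the candidate area pattern via
#' the Bhattacharyya coefficient and the same permutation test used for the
#' RSN masks, Holm-corrected over the seven comparisons.
#'
#' @param candidate unit-sum area weight vector over functional areas.
#' @param het a [heterogeneous_sc()].
#' @param parc a [parcellation()].
#' @param N,seed,alpha_sig as in [match_rsn()].
#' @return data.frame with one row per metric.
#' @export
match_graph_metrics <- function(candidate, het, parc, N = 10000L, seed = 1L,
                                alpha_sig = 0.05) {
  gm <- graph_metrics(het)
  fun <- functional_areas(parc)
  rows <- lapply(seq_along(gm), function(j) {
    v <- gm[fun, j]
    s <- sum(v)
    v <- if (s > 0) v / s else v
    mr <- permutation_test(candidate, v, N = N, seed = seed + j)
    data.frame(metric = names(gm)[j], BC = mr$BC, p = mr$p,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$p_corrected <- holm_correct(df$p)
  df$significant <- df$p_corrected < alpha_sig
  df
}

#' Cortical versus subcortical contribution tests
#'
#' Two-sample Kolmogorov-Smirnov and Wilcoxon rank-sum tests on the cortical
#' versus subcortical area weights of a responsive-network pattern, flagged
#' at the 0.01 level.
#'
#' @param candidate unit-sum weight vector over functional areas.
#' @param parc a [parcellation()].
#' @param alpha_sig significance level (default 0.01).
#' @return list with `ks_p`, `ranksum_p`, `ks_significant`,
#'   `ranksum_significant`.
#' @export
cortical_subcortical_tests <- function(candidate, parc, alpha_sig = 0.01) {
  fun <- functional_areas(parc)
  kind <- parc$areas$kind[match(fun, parc$areas$id)]
  x <- candidate[kind == "cortical"]
  y <- candidate[kind == "subcortical"]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 areas in each group", call. = FALSE)
  ks <- suppressWarnings(stats::ks.test(x, y))
  ws <- suppressWarnings(stats::wilcox.test(x, y))
  list(ks_p = ks$p.value, ranksum_p = ws$p.value,
       ks_significant = ks$p.value < alpha_sig,
       ranksum_significant = ws$p.value < alpha_sig)
}

#' Optimal parameters from a table of match results
#'
#' For every (metric, alpha, sigma) triple, take the per-RSN maximum
#' significant Bhattacharyya coefficient, average over the eight networks
#' (networks without a significant match contribute 0), and return the
#' argmax triple.  Computed separately for cortical-only, subcortical-only,
#' and combined stimulation sites.
#'
#' @param matches data.frame from [match_rsn()] rows pooled over conditions.
#' @param parc a [parcellation()] (classifies sites as cortical or
#'   subcortical).
#' @param n_rsn number of resting-state networks in the family (default 8).
#' @return list per group (`cortical`, `subcortical`, `combined`), each a
#'   one-row data.frame `metric`, `alpha`, `sigma`, `mean_BC` (or NULL when
#'   the group has no significant match).
#' @export
select_optimal_parameters <- function(matches, parc, n_rsn = 8L) {
  site_kind <- function(site)
    parc$areas$kind[match(site, parc$areas$id)]
  groups <- list(
    cortical = matches[site_kind(matches$site) == "cortical", ],
    subcortical = matches[site_kind(matches$site) == "subcortical", ],
    combined = matches)
  lapply(groups, function(df) {
    df <- df[df$significant %in% TRUE, ]
    if (!nrow(df)) return(NULL)
    key <- interaction(df$metric, df$alpha, df$sigma, drop = TRUE)
    per_triple <- lapply(split(df, key), function(d) {
      best <- vapply(split(d$BC, d$rsn), max, numeric(1))
      data.frame(metric = d$metric[1], alpha = d$alpha[1], sigma = d$sigma[1],
                 mean_BC = sum(best) / n_rsn, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, per_triple)
    tab <- tab[order(tab$metric, tab$alpha, tab$sigma), ]
    tab[which.max(tab$mean_BC), , drop = FALSE]
  })
}

#' Build the stimulation lookup map from significant matches
#'
#' One row per (site, network): the best significant match, keeping the
#' lowest candidate index on Bhattacharyya ties.  Sites are grouped as
#' cortical or subcortical.
#'
#' @param matches pooled data.frame from [match_rsn()].
#' @param parc a [parcellation()].
#' @return data.frame `site`, `site_name`, `site_kind`, `network`, `BC`,
#'   `p_corrected`, `eigenvector` (candidate id), `alpha`, `sigma` (empty
#'   when nothing is significant).
#' @export
build_stimulation_map <- function(matches, parc) {
  df <- matches[matches$significant %in% TRUE, ]
  empty <- data.frame(site = integer(0), site_name = character(0),
                      site_kind = character(0), network = character(0),
                      BC = numeric(0), p_corrected = numeric(0),
                      eigenvector = character(0), alpha = numeric(0),
                      sigma = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(df)) return(empty)
  key <- interaction(df$site, df$rsn, drop = TRUE)
  rows <- lapply(split(df, key), function(d) {
    d <- d[order(-d$BC, d$candidate), ]
    b <- d[1, ]
    data.frame(site = b$site,
               site_name = parc$areas$name[match(b$site, parc$areas$id)],
               site_kind = parc$areas$kind[match(b$site, parc$areas$id)],
               network = b$rsn, BC = b$BC, p_corrected = b$p_corrected,
               eigenvector = b$candidate, alpha = b$alpha, sigma = b$sigma,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$site_kind, out$site, out$network), ]
  rownames(out) <- NULL
  out
}
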