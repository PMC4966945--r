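#' Distribution of produced metrical levels across the cohort
#'
#' Per stimulus and movement type, the number of participants moving at the
#' beat level and at the two-beat level, plus the column medians across
#' stimuli. With an even number of stimuli the raw median is a half-integer;
#' printed medians are rounded to the nearest integer (halves to even).
#'
#' @param trials data.frame with columns \code{stimulus_name},
#'   \code{movement_type}, \code{level}.
#' @return list: \code{counts} (stimulus x movement-level count table as a
#'   data.frame) and \code{medians} (named integer medians per movement x
#'   level column).
#' @export
level_distribution_table <- function(trials) {
  keep <- trials$level %in% c("beat", "two_beat")
  tr <- trials[keep, , drop = FALSE]
  stim <- unique(trials$stimulus_name)
  counts <- do.call(rbind, lapply(stim, function(s) {
    row <- data.frame(stimulus_name = s, stringsAsFactors = FALSE)
    for (mv in c("bounce", "clap")) {
      for (lv in c("beat", "two_beat")) {
        row[[paste(mv, lv, sep = "_")]] <-
          sum(tr$stimulus_name == s & tr$movement_type == mv & tr$level == lv)
      }
    }
    row
  }))
  med <- vapply(setdiff(names(counts), "stimulus_name"), function(cn) {
    median_half_even(counts[[cn]])
  }, numeric(1))
  list(counts = counts, medians = med)
}

#' Median rounded to the nearest integer, halves to even
#'
#' @param x numeric vector.
#' @return integer-valued median.
#' @export
median_half_even <- function(x) round(stats::median(x))

#' Condition-wise synchronization success proportions
#'
#' For each participant and each of the four conditions (bouncing to music,
#' clapping to music, bouncing to metronome, clapping to metronome): the
#' proportion of trials classed normal among classifiable trials (normal +
#' poor; bimodal and level-excluded trials are removed from the
#' denominator). A condition with no classifiable trial is \code{NA}, not
#' zero.
#'
#' @param trials data.frame with columns \code{participant_id},
#'   \code{movement_type}, \code{is_metronome}, \code{trial_class}.
#' @return data.frame: \code{participant_id}, \code{bounce_music},
#'   \code{clap_music}, \code{bounce_metro}, \code{clap_metro}.
#' @export
success_profiles <- function(trials) {
  conds <- list(bounce_music = c("bounce", FALSE),
                clap_music = c("clap", FALSE),
                bounce_metro = c("bounce", TRUE),
                clap_metro = c("clap", TRUE))
  ids <- unique(trials$participant_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    row <- data.frame(participant_id = id, stringsAsFactors = FALSE)
    for (cn in names(conds)) {
      sel <- trials$participant_id == id &
        trials$movement_type == conds[[cn]][1] &
        trials$is_metronome == as.logical(conds[[cn]][2]) &
        trials$trial_class %in% c("normal", "poor")
      row[[cn]] <- if (any(sel)) {
        mean(trials$trial_class[sel] == "normal")
      } else NA_real_
    }
    row
  }))
  out
}

#' Cluster poor-synchronizer success profiles
#'
#' Two-stage clustering of the 4-condition success-proportion profiles:
#' agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distances) cut at each k in \code{k_range}, with k chosen by maximal mean
#' silhouette width; then k-means with MacQueen's sequential update,
#' initialized at the hierarchical clusters' means, to estimate the final
#' centroids. Deterministic given the data (the seed only breaks k-means
#' ties).
#'
#' @param profiles data.frame from [success_profiles()] (rows with missing
#'   proportions are dropped), or a numeric matrix.
#' @param k_range candidate cluster counts.
#' @param seed RNG seed for k-means tie-breaking.
#' @param k force a cluster count, skipping selection (\code{k = 1} returns
#'   the grand mean as the single centroid).
#' @return list: \code{k}, \code{assignments} (named by participant),
#'   \code{centroids} (k x 4 matrix), \code{silhouette} (mean widths per
#'   candidate k, \code{NA} where undefined).
#' @export
cluster_profiles <- function(profiles, k_range = 2:6, seed = 1L, k = NULL) {
  if (is.data.frame(profiles)) {
    ids <- profiles$participant_id
    m <- as.matrix(profiles[, setdiff(names(profiles), "participant_id")])
  } else {
    m <- as.matrix(profiles)
    ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  }
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  ids <- ids[keep]

  if (!is.null(k) && k == 1) {
    return(list(k = 1L, assignments = stats::setNames(rep(1L, nrow(m)), ids),
                centroids = matrix(colMeans(m), nrow = 1,
                                   dimnames = list(NULL, colnames(m))),
                silhouette = NULL))
  }
  d <- stats::dist(m)
  if (all(d < 1e-12)) {
    # all profiles identical: clustering is degenerate, everyone together
    return(list(k = 1L, assignments = stats::setNames(rep(1L, nrow(m)), ids),
                centroids = matrix(colMeans(m), nrow = 1,
                                   dimnames = list(NULL, colnames(m))),
                silhouette = NULL))
  }
  hc <- stats::hclust(d, method = "ward.D2")

  sil <- NULL
  if (is.null(k)) {
    k_range <- k_range[k_range < nrow(m)]
    if (!length(k_range)) stop("fewer profiles than the smallest candidate k")
    sil <- vapply(k_range, function(kk) {
      cl <- stats::cutree(hc, k = kk)
      if (length(unique(cl)) < 2) return(NA_real_)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    names(sil) <- k_range
    if (all(is.na(sil))) stop("silhouette undefined for every candidate k")
    k <- k_range[which.max(sil)]
  }
  if (nrow(m) < k) stop("fewer profiles than clusters")

  cl0 <- stats::cutree(hc, k = k)
  centers0 <- do.call(rbind, lapply(seq_len(k), function(g) {
    colMeans(m[cl0 == g, , drop = FALSE])
  }))
  km <- withr::with_seed(seed, {
    stats::kmeans(m, centers = centers0, algorithm = "MacQueen",
                  iter.max = 100)
  })
  list(k = k,
       assignments = stats::setNames(km$cluster, ids),
       centroids = km$centers,
       silhouette = sil)
}

#' Rank-sum (Mann-Whitney) test
#'
#' \code{U} counts the pairs \code{(a, b)} with \code{a < b} (plus 1/2 per
#' tie); the two-sided p-value uses the normal approximation with tie
#' correction. Used for cohort-level contrasts such as beat-level counts in
#' clapping versus bouncing.
#'
#' @param a,b numeric samples.
#' @return list: \code{U}, \code{z}, \code{p}.
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  # sum of a's ranks relates to pairs with a > b; invert for a < b counting
  U_greater <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U <- n1 * n2 - U_greater
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(U = U, z = 0, p = 1))
  }
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, z = z, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Weighted condition summaries of synchronization regularity
#'
#' Group-level SR summaries weight each trial by its response count, because
#' a beat-level trial contains twice as many responses as a two-beat trial
#' of the same duration.
#'
#' @param sr_table data.frame with columns \code{participant_id},
#'   \code{movement_type}, \code{stimulus_name}, \code{sr} and \code{n}
#'   (response count).
#' @return list: \code{by_condition} (weighted mean SR per movement type x
#'   stimulus), \code{by_movement} (weighted mean SR per movement type),
#'   \code{clap_minus_bounce} (per-participant difference of weighted mean
#'   SR, clapping minus bouncing).
#' @export
condition_summary <- function(sr_table) {
  wmean <- function(x, w) sum(x * w) / sum(w)
  split_by <- interaction(sr_table$movement_type, sr_table$stimulus_name,
                          drop = TRUE)
  by_condition <- do.call(rbind, lapply(split(sr_table, split_by), function(g) {
    data.frame(movement_type = g$movement_type[1],
               stimulus_name = g$stimulus_name[1],
               mean_sr = wmean(g$sr, g$n), n_trials = nrow(g))
  }))
  rownames(by_condition) <- NULL
  by_movement <- vapply(split(sr_table, sr_table$movement_type), function(g) {
    wmean(g$sr, g$n)
  }, numeric(1))
  diffs <- vapply(split(sr_table, sr_table$participant_id), function(g) {
    cl <- g[g$movement_type == "clap", ]
    bo <- g[g$movement_type == "bounce", ]
    if (!nrow(cl) || !nrow(bo)) return(NA_real_)
    wmean(cl$sr, cl$n) - wmean(bo$sr, bo$n)
  }, numeric(1))
  list(by_condition = by_condition, by_movement = by_movement,
       clap_minus_bounce = diffs)
}
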