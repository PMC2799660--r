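#' Per-TF profile feature for clustering
#'
#' Builds the averaged occupancy profile around a TF's bound sites in
#' the in vivo and the in vitro maps (window `2*half_width+1` bp,
#' mirror-averaged across the center), normalizes each profile to its
#' own mean, keeps the central `central_bp` basepairs of each, and
#' catenates in vivo then in vitro. Normalizing per profile makes the
#' feature invariant to rescaling either input map.
#'
#' @param tf TF name stored on the feature
#' @param invivo_map,invitro_map `tag_map`s on the same genome
#' @param sites bound-site data.frame for this TF
#' @param half_width profile half-width in bp
#' @param central_bp basepairs kept from the center of each profile
#' @return a `profile_feature`: list with `tf`, `feature`
#'   (length `2*central_bp`), `invivo`, `invitro` (full normalized
#'   profiles)
#' @export
build_feature <- function(tf, invivo_map, invitro_map, sites,
                          half_width = 600L, central_bp = 600L) {
  stopifnot(nrow(sites) >= 1L, central_bp <= 2L * half_width)
  norm_prof <- function(map, label) {
    p <- extract_profile(map, sites, half_width = half_width,
                         symmetrize = TRUE, label = label)
    m <- mean(p$value)
    if (m == 0) stop("zero-mean profile for ", tf)
    p$value <- p$value / m
    p
  }
  vivo <- norm_prof(invivo_map, "invivo")
  vitro <- norm_prof(invitro_map, "invitro")
  H <- half_width
  keep <- (H + 1L - central_bp %/% 2L):(H + central_bp - central_bp %/% 2L)
  structure(list(tf = tf,
                 feature = c(vivo$value[keep], vitro$value[keep]),
                 invivo = vivo, invitro = vitro),
            class = "profile_feature")
}

#' Stack profile features into a matrix
#'
#' @param features list of `profile_feature`s
#' @return numeric matrix, one row per TF
#' @export
feature_matrix <- function(features) {
  m <- do.call(rbind, lapply(features, `[[`, "feature"))
  rownames(m) <- vapply(features, `[[`, "", "tf")
  m
}

#' k-means clustering of profiles under Pearson similarity
#'
#' Rows are standardized to mean 0, SD 1 and clustered with Euclidean
#' k-means; squared Euclidean distance between z-scored rows is an
#' affine function of 1 - Pearson correlation, so this is k-means under
#' correlation similarity. The best of `n_restarts` random starts by
#' total within-cluster sum of squares is kept; a restart that produces
#' an empty cluster is re-drawn. Deterministic under `seed`.
#'
#' @param features matrix (TF x feature) or list of `profile_feature`s
#' @param k number of clusters
#' @param seed RNG seed
#' @param n_restarts random restarts
#' @param max_iter Lloyd iterations per restart
#' @return a `profile_clusters`: list with `assignment` (named integer),
#'   `centers` (on the standardized scale), `inertia`, `k`, `seed`
#' @export
kmeans_pearson <- function(features, k = 5L, seed = 1L, n_restarts = 20L,
                           max_iter = 100L) {
  x <- if (is.matrix(features)) features else feature_matrix(features)
  if (nrow(x) < k) stop("need at least k = ", k, " profiles")
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant profile row(s): ",
         paste(rownames(x)[sds == 0], collapse = ", "))
  z <- t(scale(t(x)))
  best <- NULL
  with_seed(seed, {
    done <- 0L
    tries <- 0L
    while (done < n_restarts && tries < 10L * n_restarts) {
      tries <- tries + 1L
      km <- tryCatch(
        suppressWarnings(
          stats::kmeans(z, centers = k, iter.max = max_iter,
                        algorithm = "Lloyd", nstart = 1L)),
        error = function(e) NULL)
      if (is.null(km) || length(unique(km$cluster)) < k) next
      done <- done + 1L
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stop("k-means failed to find k non-empty clusters")
  structure(list(assignment = stats::setNames(best$cluster, rownames(x)),
                 centers = best$centers,
                 inertia = best$tot.withinss,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat(sprintf("profile_clusters: k = %d, %d profiles, inertia %.3f\n",
              x$k, length(x$assignment), x$inertia))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Order TFs within clusters by blurring improvement
#'
#' Within each cluster, TFs are ranked by their resolution delta
#' (improvement in association with binding when occupancy is averaged
#' over the large window instead of the small one), descending; ties
#' break lexicographically by TF name.
#'
#' @param result a `profile_clusters`
#' @param deltas named numeric vector of per-TF deltas
#' @return data.frame with columns `tf`, `cluster`, `delta`,
#'   `rank_in_cluster`
#' @export
order_within_clusters <- function(result, deltas) {
  tfs <- names(result$assignment)
  missing <- setdiff(tfs, names(deltas))
  if (length(missing))
    stop("no delta for TF(s): ", paste(missing, collapse = ", "))
  df <- data.frame(tf = tfs,
                   cluster = unname(result$assignment),
                   delta = unname(deltas[tfs]))
  df <- df[order(df$cluster, -df$delta, df$tf), , drop = FALSE]
  df$rank_in_cluster <- stats::ave(seq_len(nrow(df)), df$cluster,
                                   FUN = seq_along)
  rownames(df) <- NULL
  df
}
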