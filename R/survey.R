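# Survey orchestration: clustering variants x edge variants x thresholds x
# subgraphs -> feature tables -> leave-one-out negative surprise.

#' Parcellate one subject according to a clustering setting
#'
#' @param subject a `subject_volume`.
#' @param setting list with `family` ("atlas", "ward" or "RGS") and the
#'   family's parameters (`labels` for atlas; `k`, `p` for ward; `T`, `p`
#'   for RGS) plus an optional `tag`.
#' @return a `parcellation`.
#' @export
parcellate <- function(subject, setting) {
  tag <- setting$tag %||% setting$family
  switch(setting$family,
         atlas = atlas_parcellate(subject, setting$labels),
         ward = ward_parcellate(subject, setting$k, setting$p %||% 1L,
                                method_tag = tag),
         RGS = rgs_select(rgs_grow(subject, setting$T %||% 0.75),
                          setting$p %||% 1L, method_tag = tag),
         stop("unknown clustering family: ", setting$family))
}

subject_graph_features <- function(graph, wmin, subgraph) {
  g <- threshold_graph(graph, wmin)
  if (subgraph == "rich") g <- rich_club_subgraph(g)
  if (!is_connected(g)) return(NULL)
  feature_vector(g)
}

#' Run the graph-construction survey on a cohort
#'
#' For every clustering setting x edge spec the cohort's graphs are built
#' once; every threshold x subgraph is then scored by leave-one-out
#' negative surprise of the multivariate-t model on the resulting feature
#' vectors. Combinations in which any subject's graph disconnects are
#' skipped and marked.
#'
#' @param cohort list of `subject_volume` (see [simulate_cohort()]).
#' @param clusterings named list of clustering settings (see
#'   [parcellate()]).
#' @param edges named list of [edge_method_spec()]s.
#' @param thresholds numeric vector of w_min values.
#' @param subgraphs subset of c("full", "rich").
#' @param prior prior over conditions (uniform by default).
#' @return list with `summary` (data.frame: clustering, edge_variant,
#'   edge_family, w_min, subgraph, status, mean_surprise, d, n_subjects)
#'   and `features` (named list of per-combination feature sets, each a
#'   named-by-condition list of matrices).
#' @export
run_survey <- function(cohort, clusterings, edges,
                       thresholds = 0, subgraphs = "full", prior = NULL) {
  manifest <- attr(cohort, "manifest")
  stopifnot(!is.null(manifest), length(clusterings) >= 1L,
            length(edges) >= 1L)
  conditions <- unique(manifest$condition)
  summary_rows <- list()
  features_out <- list()
  for (cl_name in names(clusterings)) {
    parcs <- lapply(cohort, parcellate, setting = clusterings[[cl_name]])
    tss <- Map(extract_mean_timeseries, cohort, parcs)
    for (e_name in names(edges)) {
      spec <- edges[[e_name]]
      graphs <- lapply(tss, build_graph, spec = spec)
      for (wmin in thresholds) {
        for (sg in subgraphs) {
          combo <- sprintf("%s|%s|w%.2f|%s", cl_name, e_name, wmin, sg)
          fv <- lapply(graphs, function(g) {
            tryCatch(subject_graph_features(g, wmin, sg),
                     error = function(e) NULL)
          })
          ok <- !vapply(fv, is.null, logical(1))
          if (!all(ok)) {
            summary_rows[[combo]] <- data.frame(
              clustering = cl_name, edge_variant = e_name,
              edge_family = spec$family, w_min = wmin, subgraph = sg,
              status = "skipped", mean_surprise = NA_real_,
              d = NA_integer_, n_subjects = sum(ok))
            message("skipped (disconnected): ", combo)
            next
          }
          fmat <- do.call(rbind, fv)
          by_cond <- lapply(stats::setNames(conditions, conditions),
                            function(cc) {
                              fmat[manifest$condition == cc, , drop = FALSE]
                            })
          d <- ncol(fmat)
          hyper <- hyperparams(d)
          loo <- if (is.null(prior)) loo_evaluate(by_cond, hyper) else
            loo_evaluate(by_cond, hyper, prior)
          summary_rows[[combo]] <- data.frame(
            clustering = cl_name, edge_variant = e_name,
            edge_family = spec$family, w_min = wmin, subgraph = sg,
            status = "ok", mean_surprise = loo$mean_surprise,
            d = d, n_subjects = nrow(fmat))
          features_out[[combo]] <- by_cond
        }
      }
    }
  }
  summary <- do.call(rbind, summary_rows)
  summary$combination <- names(summary_rows)
  rownames(summary) <- NULL
  list(summary = summary, features = features_out)
}

#' Long-format property table for significance scans and rank profiles
#'
#' Per subject x combination mean graph properties (mean edge weight,
#' weighted degree, shortest path, clustering coefficient), in the long
#' format [significance_scan()] and [rank_profiles()] consume.
#'
#' @inheritParams run_survey
#' @param clustering_families named character vector mapping clustering
#'   setting names to families (ward / RGS / atlas); defaults to the
#'   setting's `family` field.
#' @return data.frame with columns subject_id, condition,
#'   clustering_family, edge_family, variant, property, value.
#' @export
property_table <- function(cohort, clusterings, edges,
                           thresholds = 0, subgraphs = "full") {
  manifest <- attr(cohort, "manifest")
  stopifnot(!is.null(manifest))
  rows <- list()
  for (cl_name in names(clusterings)) {
    family_cl <- clusterings[[cl_name]]$family
    parcs <- lapply(cohort, parcellate, setting = clusterings[[cl_name]])
    tss <- Map(extract_mean_timeseries, cohort, parcs)
    for (e_name in names(edges)) {
      spec <- edges[[e_name]]
      graphs <- lapply(tss, build_graph, spec = spec)
      for (wmin in thresholds) {
        for (sg in subgraphs) {
          variant <- sprintf("%s|%s|w%.2f|%s", cl_name, e_name, wmin, sg)
          for (si in seq_along(graphs)) {
            g <- threshold_graph(graphs[[si]], wmin)
            if (sg == "rich") {
              g <- tryCatch(rich_club_subgraph(g), error = function(e) NULL)
              if (is.null(g)) next
            }
            connected <- is_connected(g)
            dists <- if (connected) shortest_path_values(g) else numeric(0)
            props <- c(
              weight = mean_edge_weight(g),
              degree = mean(degree_features(g)$deg_w),
              spath = if (connected) mean(dists[is.finite(dists)]) else NA,
              clustcoef = mean(clustering_coefficient(g)))
            for (pn in names(props)) {
              if (is.na(props[[pn]])) next
              rows[[length(rows) + 1L]] <- data.frame(
                subject_id = manifest$subject_id[si],
                condition = manifest$condition[si],
                clustering_family = family_cl, edge_family = spec$family,
                variant = variant, property = pn, value = props[[pn]])
            }
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}
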