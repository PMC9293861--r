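# Broom-style tidy()/glance() methods for result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy tlr_de
#' @export
tidy.tlr_de <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x) %in% c("feature_id", "base_mean_a", "base_mean_b",
                                               "log2_fc", "stat", "p_value", "padj")])
}

#' @method glance tlr_de
#' @export
glance.tlr_de <- function(x, lfc_min = 1, padj_max = 0.05, ...) {
  tibble::tibble(
    group_a = attr(x, "group_a"), group_b = attr(x, "group_b"),
    n_features = nrow(x),
    n_up = sum(x$log2_fc >= lfc_min & x$padj < padj_max, na.rm = TRUE),
    n_down = sum(x$log2_fc <= -lfc_min & x$padj < padj_max, na.rm = TRUE),
    dispersion_floor = attr(x, "dispersion_floor"),
    unreliable = attr(x, "unreliable")
  )
}

#' @method tidy tlr_synergy
#' @export
tidy.tlr_synergy <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method glance tlr_synergy
#' @export
glance.tlr_synergy <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_synergy = sum(x$call == "synergy"),
    n_antagonist = sum(x$call == "antagonist"),
    n_neither = sum(x$call == "neither"),
    n_undefined = sum(x$call == "undefined"),
    upper = attr(x, "upper"), lower = attr(x, "lower")
  )
}

#' @method tidy tlr_clusters
#' @export
tidy.tlr_clusters <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method glance tlr_clusters
#' @export
glance.tlr_clusters <- function(x, ...) {
  lab <- if ("label" %in% names(x)) x$label else x$cluster
  counts <- table(factor(lab, levels = attr(x, "label_set")))
  out <- tibble::as_tibble(as.list(counts))
  names(out) <- paste0("n_", names(out))
  multi <- if (all(c("rule_I", "rule_II") %in% names(x))) {
    sum(rowSums(as.matrix(x[startsWith(names(x), "rule_")])) > 1)
  } else NA_integer_
  dplyr::bind_cols(tibble::tibble(n_peaks = nrow(x)), out,
                   tibble::tibble(n_multi_rule = multi))
}

#' @method tidy tlr_secall
#' @export
tidy.tlr_secall <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method glance tlr_secall
#' @export
glance.tlr_secall <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x),
    n_super = sum(x$is_super),
    cutoff_index = attr(x, "cutoff_index"),
    cutoff_signal = attr(x, "cutoff_signal")
  )
}

#' @method tidy tlr_modules
#' @export
tidy.tlr_modules <- function(x, ...) x$assignment

#' @method glance tlr_modules
#' @export
glance.tlr_modules <- function(x, ...) {
  asg <- x$assignment
  tibble::tibble(
    n_genes = nrow(asg),
    n_modules = length(setdiff(unique(asg$module), "unassigned")),
    n_unassigned = sum(asg$module == "unassigned"),
    min_module_size = x$params$min_module_size,
    cut_height = x$params$cut_height,
    merge_cor = x$params$merge_cor
  )
}

#' @method tidy tlr_perm
#' @export
tidy.tlr_perm <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method glance tlr_perm
#' @export
glance.tlr_perm <- function(x, ...) tibble::as_tibble(unclass(x))
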