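# Per-class Dice evaluation under the binary-annotation regime, aggregation
# into grouped means +- inter-class deviations, and report serialization.

#' Per-class Dice on a held-out split
#'
#' For each class c, the model's class-c prediction mask is compared against
#' the binary ground truth on exactly the test images annotated with c, and
#' the per-class score is the mean Dice over those images. Classes with no
#' test images are recorded as absent (dropped), not as 0.
#'
#' @param model a `seg_net` knowing all registry classes.
#' @param test_set list of [annotated_image()].
#' @param registry a [class_registry()].
#' @return named numeric vector, names = class ids present in the test set.
#' @export
evaluate_split <- function(model, test_set, registry) {
  all_cls <- sort(unlist(registry$steps))
  if (inherits(model, "seg_net") && model$n_classes < max(all_cls)) {
    stop_validation("model knows %d classes but registry defines up to %d",
                    model$n_classes, max(all_cls))
  }
  scores <- list()
  for (ai in test_set) {
    pred <- predict_with_confidence(seg_forward(model, ai$image))
    pmask <- (pred$labels == ai$class_id) * 1L
    key <- as.character(ai$class_id)
    scores[[key]] <- c(scores[[key]], dice_score(pmask, ai$mask))
  }
  present <- as.character(all_cls[as.character(all_cls) %in% names(scores)])
  vapply(setNames(present, present), function(k) mean(scores[[k]]), numeric(1))
}

#' Grouped means and inter-class deviations of per-class Dice
#'
#' For each named class group, the arithmetic mean and the population
#' (N-divisor) standard deviation across the group's per-class values --
#' the "mean +- inter-category deviation" layout of incremental-segmentation
#' result tables. `sd_type = "sample"` switches to the N-1 divisor.
#'
#' @param per_class named numeric vector of per-class values (names =
#'   class ids).
#' @param groups named list of integer class-id vectors, e.g.
#'   `list("1-7" = 1:7, "8-11" = 8:11, "1-11" = 1:11)`.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return named list: each group maps to `c(mean, sd)`.
#' @export
#' @examples
#' aggregate_group_means(c("1" = 80, "2" = 60), list(all = 1:2))
aggregate_group_means <- function(per_class, groups,
                                  sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  lapply(groups, function(ids) {
    keys <- as.character(ids)
    miss <- keys[!keys %in% names(per_class)]
    if (length(miss)) {
      stop_validation("class %s missing from per-class values",
                      paste(miss, collapse = ","))
    }
    v <- unname(per_class[keys])
    n <- length(v)
    dev <- if (n == 1) 0 else if (sd_type == "population") {
      sqrt(mean((v - mean(v))^2))
    } else {
      stats::sd(v)
    }
    c(mean = mean(v), sd = dev)
  })
}

#' Assemble a per-step evaluation report
#'
#' @param per_class named per-class Dice vector (see [evaluate_split()]).
#' @param groups named list of class-id groups.
#' @param t step index.
#' @param method method tag, e.g. `"fine-tune"` or `"kd+dg+cl"`.
#' @param sd_type deviation convention (see [aggregate_group_means()]).
#' @return a `step_report` object.
#' @export
step_report <- function(per_class, groups, t, method = "kd+dg+cl",
                        sd_type = "population") {
  structure(list(t = as.integer(t), method = method,
                 per_class_dice = per_class,
                 group_means = aggregate_group_means(per_class, groups, sd_type),
                 groups = groups),
            class = "step_report")
}

#' @export
print.step_report <- function(x, ...) {
  cat(sprintf("<step_report> step %d, method %s\n", x$t, x$method))
  for (g in names(x$group_means)) {
    cat(sprintf("  %-8s %6.2f ± %.2f\n", g,
                x$group_means[[g]]["mean"], x$group_means[[g]]["sd"]))
  }
  invisible(x)
}

#' Write evaluation reports as JSON plus an aligned text table
#'
#' The JSON file keeps full-precision values and round-trips losslessly
#' through [read_report()]; the companion `.txt` table renders grouped means
#' with "+-" deviations rounded to 2 decimals.
#'
#' @param reports non-empty list of [step_report()] objects.
#' @param path output JSON path; the text table goes to the same path with a
#'   `.txt` extension.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path) {
  if (length(reports) == 0) stop_validation("empty report list")
  payload <- lapply(reports, function(r) {
    list(t = r$t, method = r$method,
         per_class_dice = as.list(r$per_class_dice),
         groups = lapply(r$groups, as.integer),
         group_means = lapply(r$group_means, function(gm) {
           list(mean = unname(gm["mean"]), sd = unname(gm["sd"]))
         }))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(format_report_table(reports),
             sub("\\.json$", ".txt", path))
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path JSON path.
#' @return list of `step_report` objects.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(r) {
    per_class <- unlist(r$per_class_dice)
    groups <- lapply(r$groups, function(g) as.integer(unlist(g)))
    rep <- step_report(per_class, groups, r$t, r$method)
    # keep the stored means (identical up to serialization precision)
    rep$group_means <- lapply(r$group_means, function(gm) {
      c(mean = gm$mean, sd = gm$sd)
    })
    rep
  })
}

#' Render reports as an aligned text table
#'
#' One row per (method, step), one column per class group, cells formatted
#' `mean +- sd` at 2 decimals.
#'
#' @param reports list of [step_report()] objects sharing one group layout.
#' @return character vector of table lines.
#' @export
format_report_table <- function(reports) {
  gnames <- unique(unlist(lapply(reports, function(r) names(r$group_means))))
  header <- sprintf("%-12s %-5s %s", "method", "step",
                    paste(sprintf("%-16s", gnames), collapse = ""))
  rows <- vapply(reports, function(r) {
    cells <- vapply(gnames, function(g) {
      gm <- r$group_means[[g]]
      cell <- if (is.null(gm)) "-" else
        sprintf("%.2f ± %.2f", gm["mean"], gm["sd"])
      sprintf("%-16s", cell)
    }, character(1))
    sprintf("%-12s %-5d %s", r$method, r$t, paste(cells, collapse = ""))
  }, character(1))
  c(header, strrep("-", nchar(header)), rows)
}
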