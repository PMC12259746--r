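#' Confusion matrix between predicted and validated class labels
#'
#' Rows are the predicted class, columns the validated (reference) class.
#' This orientation matters: transposing it swaps commission and omission
#' errors, so it is fixed here and documented.
#'
#' @param predicted,validated either two `hab_landcover` layers on the same
#'   grid (cells where both are non-nodata are cross-tabulated) or two
#'   equal-length label vectors.
#' @param classes optional class-name ordering; defaults to the union of the
#'   legends/labels in order of appearance.
#' @return an object of class `hab_confusion`: the count matrix `C` with row
#'   sums `R`, column sums `P` and grand total `N`.
#' @export
build_confusion <- function(predicted, validated, classes = NULL) {
  if (inherits(predicted, "hab_landcover")) {
    if (!inherits(validated, "hab_landcover")) {
      stop("validated must also be a hab_landcover", call. = FALSE)
    }
    gp <- predicted$grid; gv <- validated$grid
    if (gp$n_rows != gv$n_rows || gp$n_cols != gv$n_cols ||
        gp$cell_size != gv$cell_size || any(gp$origin != gv$origin)) {
      stop("predicted and validated grids have different geometry",
           call. = FALSE)
    }
    pred <- landcover_classes(predicted)
    val <- landcover_classes(validated)
  } else {
    pred <- as.character(predicted)
    val <- as.character(validated)
    if (length(pred) != length(val)) {
      stop("predicted and validated must have equal length", call. = FALSE)
    }
  }
  keep <- !is.na(pred) & !is.na(val)
  if (!any(keep)) stop("no overlapping labeled cells", call. = FALSE)
  pred <- pred[keep]; val <- val[keep]
  if (is.null(classes)) classes <- unique(c(pred, val))
  lv <- factor(pred, levels = classes)
  lw <- factor(val, levels = classes)
  C <- unclass(table(predicted = lv, validated = lw))
  new_confusion(C)
}

new_confusion <- function(C) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("confusion matrix must be square")
  if (any(C < 0)) stop("confusion counts must be nonnegative")
  structure(list(C = C, R = rowSums(C), P = colSums(C), N = sum(C),
                 classes = rownames(C)),
            class = "hab_confusion")
}

#' Construct a confusion matrix from raw counts
#'
#' @param C square nonnegative count matrix, rows = predicted,
#'   columns = validated.
#' @return a `hab_confusion`.
#' @export
confusion_matrix <- function(C) {
  if (is.null(rownames(C))) {
    dimnames(C) <- list(paste0("class", seq_len(nrow(C))),
                        paste0("class", seq_len(nrow(C))))
  }
  new_confusion(C)
}

#' @export
print.hab_confusion <- function(x, ...) {
  cat("<hab_confusion> rows = predicted, columns = validated\n")
  print(cbind(x$C, Total = x$R))
  cat("Total:", paste(x$P, collapse = " "), "| N =", x$N, "\n")
  invisible(x)
}

#' Accuracy, kappa and per-class commission/omission errors
#'
#' Overall accuracy is the diagonal fraction `sum(C_ii)/N`. Cohen's kappa is
#' the chance-corrected agreement
#' `(N * sum(C_ii) - sum(R_i * P_i)) / (N^2 - sum(R_i * P_i))`.
#' Commission error of class i is `1 - C_ii / P_i` (against the validated
#' column total) and omission error is `1 - C_ii / R_i` (against the
#' predicted row total). Classes with a zero marginal get NA for the affected
#' error with a warning, and kappa is defined as 0 (with a warning) when the
#' chance-agreement denominator degenerates (`N^2 == sum(R_i * P_i)`).
#'
#' @param cm a `hab_confusion`.
#' @return list with `accuracy`, `kappa`, and a per-class data.frame
#'   `per_class` with commission and omission errors.
#' @export
accuracy_metrics <- function(cm) {
  stopifnot(inherits(cm, "hab_confusion"))
  if (cm$N == 0) stop("empty confusion matrix", call. = FALSE)
  D <- sum(diag(cm$C))
  S <- sum(cm$R * cm$P)
  accuracy <- D / cm$N
  denom <- cm$N^2 - S
  if (denom == 0) {
    warning("degenerate kappa denominator (single effective class); kappa = 0")
    kappa <- 0
  } else {
    kappa <- (cm$N * D - S) / denom
  }
  if (any(cm$P == 0) || any(cm$R == 0)) {
    warning("zero marginal for class(es): ",
            paste(cm$classes[cm$P == 0 | cm$R == 0], collapse = ", "),
            "; commission/omission NA there")
  }
  commission <- ifelse(cm$P > 0, 1 - diag(cm$C) / cm$P, NA_real_)
  omission <- ifelse(cm$R > 0, 1 - diag(cm$C) / cm$R, NA_real_)
  list(accuracy = accuracy, kappa = kappa,
       per_class = data.frame(class = cm$classes,
                              commission = unname(commission),
                              omission = unname(omission),
                              stringsAsFactors = FALSE))
}

#' Export a confusion matrix as labeled CSV
#'
#' @param cm a `hab_confusion`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(cm, path) {
  out <- cbind(as.data.frame(cm$C), Total = cm$R)
  out <- rbind(out, Total = c(cm$P, cm$N))
  write.csv(out, path)
  invisible(path)
}
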