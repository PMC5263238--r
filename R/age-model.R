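#' @importFrom stats lm.fit pf model.matrix setNames
NULL

#' Specify a stepwise age-associative model
#'
#' @param candidate_genes character vector of candidate gene ids (typically
#'   one cell type's markers).
#' @param covariates character vector naming forced-in categorical cohort
#'   covariates (columns of the covariate data supplied at fit time), e.g.
#'   \code{c("bank", "cause_of_death")}; never removable.
#' @param allow_interactions consider pairwise products of already-selected
#'   genes as candidate terms.
#' @param entry_p,removal_p partial-F p-value thresholds for adding /
#'   removing a term; \code{entry_p < removal_p} is required (defaults
#'   0.05 / 0.10).
#' @param max_terms maximum number of selected gene/interaction terms.
#' @param criterion \code{"partialF"} (default) or \code{"AIC"}.
#' @return a list of class \code{AgeModelSpec}.
#' @export
ageModelSpec <- function(candidate_genes,
                         covariates = c("bank", "cause_of_death"),
                         allow_interactions = FALSE,
                         entry_p = 0.05, removal_p = 0.10,
                         max_terms = 10L,
                         criterion = c("partialF", "AIC")) {
  criterion <- match.arg(criterion)
  if (length(candidate_genes) < 1)
    stop("need at least one candidate gene", call. = FALSE)
  .assertScalarNumber(entry_p, "entry_p", lower = 0, upper = 1)
  .assertScalarNumber(removal_p, "removal_p", lower = 0, upper = 1)
  if (entry_p >= removal_p)
    stop("entry_p must be smaller than removal_p", call. = FALSE)
  .assertScalarNumber(max_terms, "max_terms", lower = 1)
  structure(list(candidate_genes = as.character(candidate_genes),
                 covariates = as.character(covariates),
                 allow_interactions = isTRUE(allow_interactions),
                 entry_p = entry_p, removal_p = removal_p,
                 max_terms = as.integer(max_terms),
                 criterion = criterion),
            class = "AgeModelSpec")
}

## Build the numeric column for one term ("gene" or "geneA:geneB").
.termColumn <- function(term, expr) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  miss <- setdiff(parts, rownames(expr))
  if (length(miss))
    stop("gene(s) not in expression matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(parts) == 1) expr[parts, ] else expr[parts[1], ] * expr[parts[2], ]
}

## Forced covariate design (dummy coding, intercept included); drops
## redundant collinear columns with a warning.
.covariateDesign <- function(covariate_data, covariates, n) {
  if (length(covariates) == 0)
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  stopifnot(!is.null(covariate_data),
            all(covariates %in% colnames(covariate_data)))
  df <- as.data.frame(covariate_data)[, covariates, drop = FALSE]
  df[] <- lapply(df, factor)
  X <- model.matrix(~ ., df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    warning("dropping redundant covariate column(s): ",
            paste(drop, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  X
}

## OLS residual sum of squares for a design matrix.
.rss <- function(X, y) {
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Fit a stepwise age-associative regression
#'
#' Forward-backward stepwise ordinary least squares of age (years) on gene
#' expression. Cohort covariates are forced in; candidate terms are the gene
#' main effects plus (optionally) pairwise products of already-selected
#' genes. A term enters when its partial-F p-value is the smallest among
#' candidates and below \code{entry_p}; a selected term is removed when its
#' partial-F p rises above \code{removal_p}. A term removed in one step may
#' not re-enter on the next step (cycle protection). In AIC mode, additions
#' and removals are instead accepted when they lower the AIC.
#'
#' @param expression genes x samples numeric matrix.
#' @param ages numeric vector of ages (years), one per sample (>= 10
#'   samples).
#' @param spec an \code{\link{ageModelSpec}}.
#' @param covariate_data data.frame (samples x covariates) holding the
#'   forced covariate columns named in the spec; may be \code{NULL} when the
#'   spec lists none.
#' @return an \linkS4class{AgeModelFit}.
#' @seealso \code{\link{predictAge}}, \code{\link{compareCelltypeModels}}
#' @export
fitStepwiseAgeModel <- function(expression, ages, spec,
                                covariate_data = NULL) {
  stopifnot(inherits(spec, "AgeModelSpec"), is.matrix(expression),
            length(ages) == ncol(expression))
  n <- length(ages)
  if (n < 10) stop("need at least 10 samples", call. = FALSE)
  miss <- setdiff(spec$candidate_genes, rownames(expression))
  if (length(miss))
    stop("candidate gene(s) missing from matrix: ",
         paste(utils::head(miss), collapse = ", "), call. = FALSE)

  X0 <- .covariateDesign(covariate_data, spec$covariates, n)
  y <- as.numeric(ages)
  tss <- sum((y - mean(y))^2)
  cov_rss <- .rss(X0, y)
  covariate_r2 <- if (tss > 0) 1 - cov_rss / tss else 0

  selected <- character()
  just_removed <- character()
  term_cols <- function(terms) {
    if (length(terms) == 0) return(NULL)
    do.call(cbind, lapply(terms, .termColumn, expr = expression))
  }
  design <- function(terms) {
    tc <- term_cols(terms)
    if (is.null(tc)) X0 else {
      colnames(tc) <- terms
      cbind(X0, tc)
    }
  }
  aic_of <- function(rss, p) n * log(rss / n) + 2 * p

  trace <- list()
  log_step <- function(action, term, p) {
    trace[[length(trace) + 1L]] <<- data.frame(
      action = action, term = term, p = p, stringsAsFactors = FALSE)
  }

  for (step in seq_len(200L)) {
    changed <- FALSE
    removed_now <- character()

    ## backward pass
    if (length(selected) > 0) {
      X1 <- design(selected)
      rss1 <- .rss(X1, y)
      df2 <- n - ncol(X1)
      drop_p <- vapply(selected, function(tm) {
        rss0 <- .rss(design(setdiff(selected, tm)), y)
        if (spec$criterion == "AIC") {
          ## encode "removal improves AIC" as pseudo-p above/below threshold
          if (aic_of(rss0, ncol(X1) - 1) < aic_of(rss1, ncol(X1))) 1 else 0
        } else {
          Fv <- (rss0 - rss1) / (rss1 / df2)
          pf(max(Fv, 0), 1, df2, lower.tail = FALSE)
        }
      }, numeric(1))
      worst <- which.max(drop_p)
      if (drop_p[worst] > spec$removal_p) {
        removed_now <- selected[worst]
        log_step("remove", selected[worst], drop_p[worst])
        selected <- selected[-worst]
        changed <- TRUE
      }
    }

    ## forward pass
    candidates <- setdiff(spec$candidate_genes, selected)
    if (spec$allow_interactions && length(selected) >= 2) {
      sel_genes <- selected[!grepl(":", selected, fixed = TRUE)]
      if (length(sel_genes) >= 2) {
        pairs <- utils::combn(sort(sel_genes), 2)
        inter <- apply(pairs, 2, paste, collapse = ":")
        candidates <- c(candidates, setdiff(inter, selected))
      }
    }
    candidates <- setdiff(candidates, just_removed)
    if (length(selected) < spec$max_terms && length(candidates) > 0) {
      X1 <- design(selected)
      rss0 <- .rss(X1, y)
      df2 <- n - ncol(X1) - 1
      add_p <- vapply(candidates, function(tm) {
        rss1 <- .rss(cbind(X1, .termColumn(tm, expression)), y)
        if (spec$criterion == "AIC") {
          if (aic_of(rss1, ncol(X1) + 1) < aic_of(rss0, ncol(X1))) 0 else 1
        } else {
          Fv <- (rss0 - rss1) / (rss1 / df2)
          pf(max(Fv, 0), 1, df2, lower.tail = FALSE)
        }
      }, numeric(1))
      best <- which.min(add_p)
      if (add_p[best] < spec$entry_p) {
        log_step("add", candidates[best], add_p[best])
        selected <- c(selected, candidates[best])
        changed <- TRUE
      }
    }

    just_removed <- removed_now
    if (!changed) break
  }

  Xf <- design(selected)
  fit <- lm.fit(Xf, y)
  rssf <- sum(fit$residuals^2)
  r2 <- if (tss > 0) 1 - rssf / tss else 0
  p <- ncol(Xf)
  adj <- if (n - p > 0 && tss > 0) 1 - (rssf / (n - p)) / (tss / (n - 1))
         else NA_real_
  methods::new("AgeModelFit",
               terms = selected,
               coefficients = setNames(fit$coefficients, colnames(Xf)),
               r2 = max(0, min(1, r2)), adjR2 = adj,
               covariateR2 = max(0, min(1, covariate_r2)),
               fitted = as.numeric(Xf %*% ifelse(is.na(fit$coefficients), 0,
                                                 fit$coefficients)),
               spec = c(unclass(spec),
                        list(covariate_columns = colnames(X0))),
               trace = if (length(trace)) do.call(rbind, trace) else
                 data.frame(action = character(), term = character(),
                            p = numeric()))
}

#' Predict age from a stepwise fit
#'
#' @param fit an \linkS4class{AgeModelFit}.
#' @param expression genes x samples matrix containing every gene used by the
#'   fit (a missing gene is an error naming it).
#' @param covariate_data data.frame with the covariate columns used at fit
#'   time (required when the fit includes covariates).
#' @return numeric vector of predicted ages (years), one per sample.
#' @export
predictAge <- function(fit, expression, covariate_data = NULL) {
  stopifnot(methods::is(fit, "AgeModelFit"), is.matrix(expression))
  n <- ncol(expression)
  X0 <- .covariateDesign(covariate_data, fit@spec$covariates, n)
  miss <- setdiff(colnames(X0), fit@spec$covariate_columns)
  if (length(miss))
    stop("covariate level(s) unseen at fit time: ",
         paste(miss, collapse = ", "), call. = FALSE)
  ## align to training covariate columns (unseen data may lack some levels)
  Xc <- matrix(0, n, length(fit@spec$covariate_columns),
               dimnames = list(NULL, fit@spec$covariate_columns))
  Xc[, colnames(X0)] <- X0
  X <- Xc
  if (length(fit@terms)) {
    tc <- do.call(cbind, lapply(fit@terms, .termColumn, expr = expression))
    colnames(tc) <- fit@terms
    X <- cbind(X, tc)
  }
  beta <- fit@coefficients[colnames(X)]
  beta[is.na(beta)] <- 0
  as.numeric(X %*% beta)
}

#' Rank per-cell-type age models
#'
#' @param fits named list of \linkS4class{AgeModelFit} objects (>= 1), one
#'   per cell type.
#' @return data.frame sorted by decreasing R-squared (ties broken by fewer
#'   selected gene terms): \code{cell_type}, \code{r2}, \code{adj_r2},
#'   \code{n_gene_terms}.
#' @export
compareCelltypeModels <- function(fits) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)),
            all(vapply(fits, methods::is, logical(1), "AgeModelFit")))
  tab <- data.frame(
    cell_type = names(fits),
    r2 = vapply(fits, modelR2, numeric(1)),
    adj_r2 = vapply(fits, function(f) f@adjR2, numeric(1)),
    n_gene_terms = vapply(fits, function(f) length(f@terms), integer(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$r2, tab$n_gene_terms, tab$cell_type), ]
  rownames(tab) <- NULL
  tab
}
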