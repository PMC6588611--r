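#' Expression-signature HRD / PARPi-sensitivity classification
#'
#' The classifier re-implements the two-stage procedure applied to the
#' tumor expression arrays: (1) restrict the normalized (log-scale)
#' expression matrix to a signature gene list and two-way hierarchically
#' cluster it, cutting the sample dendrogram at k = 2; (2) label the
#' cluster with the lower mean signature expression DEFICIENT (the
#' signatures are framed as down-regulation of repair capacity; the
#' labelling is overridable); (3) train a k-nearest-neighbour classifier
#' on the labelled samples and classify every sample, reporting the
#' majority-vote fraction as confidence. Defaults: average linkage,
#' Euclidean distance on the log-scale values, k = 5. Predictive value is
#' estimated by leave-one-out cross-validation.
#'
#' The published signature gene lists are not reproduced in the source;
#' the package ships a synthetic default list
#' ([synthetic_signature_genes()]) purely so the machinery is testable —
#' supply real lists via [read_signature_genes()].
#'
#' @name hrd_expression
NULL

restrict_to_signature <- function(mat, signature_genes) {
  missing <- setdiff(signature_genes, rownames(mat))
  if (length(missing) > 0) {
    stop("signature gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mat[signature_genes, , drop = FALSE]
}

#' Read a signature gene list (plain text, one gene per line)
#'
#' @param path text file; blank lines and `#` comments ignored.
#' @return character vector of gene symbols.
#' @export
read_signature_genes <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Two-way hierarchical clustering restricted to a signature
#'
#' @param mat numeric expression matrix, genes x samples, log scale, no
#'   missing values (missing values are rejected at ingestion, not
#'   imputed).
#' @param signature_genes genes defining the distance space; all must be
#'   present.
#' @param linkage agglomeration method for [stats::hclust()], default
#'   `"average"`.
#' @param distance distance for [stats::dist()], default `"euclidean"`.
#' @return list: `sample_cluster` (named integer vector, values 1/2),
#'   `sample_order`, `gene_order` (dendrogram display orders),
#'   `sample_hclust`.
#' @export
cluster_two_way <- function(mat, signature_genes, linkage = "average",
                            distance = "euclidean") {
  if (ncol(mat) < 2) stop("need at least 2 samples to cluster", call. = FALSE)
  if (anyNA(mat)) stop("expression matrix contains missing values",
                       call. = FALSE)
  sub <- restrict_to_signature(mat, signature_genes)
  hs <- stats::hclust(stats::dist(t(sub), method = distance),
                      method = linkage)
  hg <- if (nrow(sub) >= 2) {
    stats::hclust(stats::dist(sub, method = distance), method = linkage)
  } else NULL
  cl <- stats::cutree(hs, k = 2)
  list(sample_cluster = cl, sample_order = hs$order,
       gene_order = if (is.null(hg)) seq_len(nrow(sub)) else hg$order,
       sample_hclust = hs)
}

#' Label clusters DEFICIENT / NORMAL by signature centroid
#'
#' The cluster whose mean signature-gene expression (centroid mean) is
#' lower is labelled DEFICIENT. Equal centroids are a tie: everything is
#' labelled NORMAL with a warning. Override with `deficient_cluster`.
#'
#' @param clusters `sample_cluster` from [cluster_two_way()].
#' @param mat the expression matrix.
#' @param signature_genes the signature list.
#' @param deficient_cluster optional 1 or 2, forcing which cluster is
#'   DEFICIENT.
#' @return named character vector (DEFICIENT/NORMAL) over samples.
#' @export
derive_labels <- function(clusters, mat, signature_genes,
                          deficient_cluster = NULL) {
  if (!all(1:2 %in% clusters)) stop("degenerate clustering: a cluster is empty",
                                    call. = FALSE)
  sub <- restrict_to_signature(mat, signature_genes)
  centroid <- vapply(1:2, function(k) {
    mean(sub[, clusters == k, drop = FALSE])
  }, 0)
  if (is.null(deficient_cluster)) {
    if (centroid[1] == centroid[2]) {
      warning("cluster centroids are equal; labelling all samples NORMAL",
              call. = FALSE)
      labels <- rep("NORMAL", length(clusters))
      names(labels) <- names(clusters)
      return(labels)
    }
    deficient_cluster <- which.min(centroid)
  }
  labels <- ifelse(clusters == deficient_cluster, "DEFICIENT", "NORMAL")
  names(labels) <- names(clusters)
  labels
}

#' Train the signature-restricted KNN classifier
#'
#' @param mat expression matrix (genes x samples) holding the training
#'   samples.
#' @param labels named character vector over the training samples (two
#'   classes required).
#' @param signature_genes genes defining the feature space.
#' @param k odd neighbour count, `k <= n - 1`; default 5.
#' @return an object of class `knn_classifier`.
#' @export
train_knn <- function(mat, labels, signature_genes, k = 5) {
  sub <- restrict_to_signature(mat, signature_genes)
  stopifnot(identical(colnames(sub), names(labels)))
  if (length(unique(labels)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (k %% 2 == 0) stop("k must be odd", call. = FALSE)
  if (k > ncol(sub) - 1) stop("k must be at most n - 1", call. = FALSE)
  structure(list(train = t(sub), labels = labels,
                 signature_genes = signature_genes, k = k),
            class = "knn_classifier")
}

## Majority vote over the k nearest training rows. Distance ties are broken
## by training order (stable), vote ties cannot arise for two classes and
## odd k.
knn_vote <- function(classifier, query, exclude = 0L) {
  d <- sqrt(colSums((t(classifier$train) - query)^2))
  if (exclude > 0L) d[exclude] <- Inf
  nn <- order(d)[seq_len(classifier$k)]
  votes <- table(classifier$labels[nn])
  winner <- names(votes)[which.max(votes)]
  list(label = winner, confidence = max(votes) / classifier$k)
}

#' Classify samples with a trained KNN classifier
#'
#' One call per sample per classifier; run once with the HRD classifier
#' and once with the PARPi-sensitivity classifier for the two independent
#' statuses.
#'
#' @param classifier a `knn_classifier`.
#' @param mat expression matrix containing the classifier's signature
#'   genes.
#' @return data.frame `sample_id`, `status` (DEFICIENT/NORMAL), and
#'   `confidence` (majority-vote fraction, always >= 0.5).
#' @export
classify_samples <- function(classifier, mat) {
  sub <- restrict_to_signature(mat, classifier$signature_genes)
  res <- lapply(seq_len(ncol(sub)), function(j) knn_vote(classifier, sub[, j]))
  data.frame(sample_id = colnames(sub),
             status = vapply(res, `[[`, "", "label"),
             confidence = vapply(res, `[[`, 0, "confidence"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Leave-one-out predictive value of a KNN classifier
#'
#' @param classifier a `knn_classifier`.
#' @return fraction of training samples whose held-out prediction matches
#'   their label.
#' @export
loo_predictive_value <- function(classifier) {
  n <- nrow(classifier$train)
  hits <- vapply(seq_len(n), function(i) {
    knn_vote(classifier, classifier$train[i, ], exclude = i)$label ==
      classifier$labels[i]
  }, NA)
  mean(hits)
}

#' Full HRD + PARPi classification of an expression matrix
#'
#' Runs cluster -> label -> KNN for the HRD signature and the PARPi
#' signature independently and joins the calls.
#'
#' @param mat expression matrix (genes x samples).
#' @param hrd_genes,parpi_genes signature gene lists.
#' @param k KNN neighbour count, default 5.
#' @return data.frame with `sample_id`, `hrd_status`
#'   (DEFICIENT/NORMAL), `hrd_confidence`, `parpi_status`
#'   (SENSITIVE/INSENSITIVE), `parpi_confidence`; attributes
#'   `hrd_loo` and `parpi_loo` hold the leave-one-out predictive values.
#' @export
hrd_classify <- function(mat, hrd_genes, parpi_genes = hrd_genes, k = 5) {
  one <- function(genes) {
    cl <- cluster_two_way(mat, genes)
    labels <- derive_labels(cl$sample_cluster, mat, genes)
    clf <- train_knn(mat, labels, genes, k = k)
    list(calls = classify_samples(clf, mat), loo = loo_predictive_value(clf))
  }
  hrd <- one(hrd_genes)
  parpi <- one(parpi_genes)
  out <- data.frame(sample_id = hrd$calls$sample_id,
                    hrd_status = hrd$calls$status,
                    hrd_confidence = hrd$calls$confidence,
                    parpi_status = ifelse(parpi$calls$status == "DEFICIENT",
                                          "SENSITIVE", "INSENSITIVE"),
                    parpi_confidence = parpi$calls$confidence,
                    stringsAsFactors = FALSE)
  attr(out, "hrd_loo") <- hrd$loo
  attr(out, "parpi_loo") <- parpi$loo
  out
}

#' Chance-corrected agreement between calls and hidden labels
#'
#' For two balanced classes: accuracy maximised over the label swap,
#' rescaled so 0 is chance and 1 is perfect recovery.
#'
#' @param calls,truth character vectors of equal length, two classes each.
#' @return adjusted agreement in \[0, 1\].
#' @export
label_agreement <- function(calls, truth) {
  acc <- mean(calls == truth)
  2 * max(acc, 1 - acc) - 1
}

#' HRD / PARPi co-occurrence with tumor two-hit evidence
#'
#' Among tumors whose germline variant in an HR-superpathway gene shows
#' LOH or a somatic second hit, what fraction are classified HR-deficient,
#' and what fraction PARPi-sensitive?
#'
#' @param hrd_calls output of [hrd_classify()] (sample_id = patient_id).
#' @param second_hits output of [second_hit_table()].
#' @param panel a `gene_panel`.
#' @return list with `n` (denominator), `n_hrd`, `frac_hrd`, `n_parpi`,
#'   `frac_parpi`; fractions NA when the denominator is empty.
#' @export
hrd_cooccurrence <- function(hrd_calls, second_hits, panel) {
  pw <- hr_super_pathway(panel_lookup(second_hits$gene, panel, "pathway"))
  hit <- second_hits$category %in% c("LOH", "SOMATIC_SECOND_HIT") & pw == "HR"
  patients <- unique(second_hits$patient_id[hit])
  patients <- patients[patients %in% hrd_calls$sample_id]
  n <- length(patients)
  if (n == 0) {
    return(list(n = 0L, n_hrd = 0L, frac_hrd = NA_real_,
                n_parpi = 0L, frac_parpi = NA_real_))
  }
  idx <- match(patients, hrd_calls$sample_id)
  n_hrd <- sum(hrd_calls$hrd_status[idx] == "DEFICIENT")
  n_parpi <- sum(hrd_calls$parpi_status[idx] == "SENSITIVE")
  list(n = n, n_hrd = n_hrd, frac_hrd = n_hrd / n,
       n_parpi = n_parpi, frac_parpi = n_parpi / n)
}

#' Packaged synthetic signature gene lists
#'
#' Stand-ins for the unpublished HRD and PARPi-sensitivity signature gene
#' lists; synthetic symbols (`SIGHRD001`...) so they can never collide
#' with real genes. For pipeline exercise only.
#'
#' @param which `"hrd"` or `"parpi"`.
#' @param n number of signature genes, default 20.
#' @return character vector of synthetic gene symbols.
#' @export
synthetic_signature_genes <- function(which = c("hrd", "parpi"), n = 20) {
  which <- match.arg(which)
  sprintf("SIG%s%03d", toupper(which), seq_len(n))
}
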