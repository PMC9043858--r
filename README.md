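# scRMTL

Supervised cell-type annotation for single-cell RNA sequencing (scRNA-seq)
count matrices by **regularized multi-task learning (RMTL)**.

Annotating cells is the first interpretive step of any scRNA-seq analysis.
Unsupervised clustering followed by manual marker-gene lookup is slow,
irreproducible and biased toward known markers. When a labeled reference
atlas exists, cell typing becomes a supervised problem — but fitting each
cell type's classifier in isolation ignores that cell populations share most
of their transcriptional program. scRMTL learns all cell types *jointly*:
each type is a binary one-vs-rest task, and the tasks are coupled through
shared regularized structure, so information about what makes a cell "a
blood cell at all" is pooled while each task keeps its own discriminative
offset. It is aimed at analysts with a labeled reference matrix who want
reproducible, automatic labels on query data.

## The model

Each task *t* ∈ {1, …, T} is the binary problem "is this cell of type *t*?"
over a common design matrix X (cells × genes, log-normalized expression)
with labels y ∈ {+1, −1}. The task weight vector decomposes as

    w_t = W0 + V_t

with W0 a shared component and V_t a task-specific offset. The default
(`shared_offset`) objective is

    min_{W0, V, b}  Σ_t (1/n_t) Σ_i L(y_it, x_i·(W0 + V_t) + b_t)
                    + λ1 ‖W0‖²  +  λ2 Σ_t ‖V_t‖²

with L the logistic loss (squared hinge available). λ1 controls the size of
the shared component and λ2 the task relatedness: λ2 → ∞ collapses all tasks
onto one pooled linear model, λ1 → ∞ decouples them into independent ridge
classifiers. Both λ's can be chosen by stratified cross-validation
(`cv_select_lambdas()`).

The alternative `l21` regularizer penalizes the stacked weight matrix W
(tasks × genes) by the L2,1 group norm λ1 Σ_j ‖W·j‖₂ plus a ridge term
λ2 ‖W‖²_F, selecting genes jointly across all cell types. Both modes are
solved by monotone FISTA (accelerated proximal gradient with backtracking
line search); the ridge and group penalties are applied through their exact
proximal maps, so the objective trace is non-increasing and extreme
penalties are handled without step-size collapse. Prediction is the argmax
of the per-task decision scores.

The package also ships:

* the quality-control pipeline: *good cells* (> 1,000 detected genes),
  *expressed genes* (count > 5 in ≥ 10% of good cells), library-size
  normalization (pluggable), log2(x+1) transform;
* the evaluation protocols: repeated stratified 8:2 splits,
  training-fraction curves (20–100% in steps of 20%), per-class
  recall/precision, 10-fold CV stability with 9:1 inner splits and Wilcoxon
  rank-sum comparison (exact enumeration for small tie-free samples);
* a gamma-Poisson count simulator (Splat-style: gamma gene means,
  log-normal DE factors and library sizes, Poisson sampling, calibrated
  logistic dropout) with the four benchmark presets `data1`–`data4`
  (500–2,000 cells, 2–5 groups, 2,000 genes, dropout 0.2);
* readers/writers for dense CSV/TSV and 10x-style MatrixMarket sparse
  counts, and a JSON model container.

## Worked example

Simulate the `data1` benchmark (500 cells, 2,000 genes, two equally likely
groups, 20% dropout) with strong differential expression, preprocess, train,
and score held-out cells:

```r
library(scRMTL)

sim  <- simulate_counts(sim_preset("data1", seed = 7, de_facLoc = 1))
expr <- preprocess_pipeline(sim$counts)   # QC filters + normalize + log2
data <- labeled_dataset(expr, sim$labels[match(expr$cell_ids, sim$counts$cell_ids)])

sp  <- split_train_test(data, test_fraction = 0.2, seed = 7)  # stratified 8:2
fit <- train_celltyper(sp$train, rmtl_config(lambda1 = 0.01, lambda2 = 0.01))
fit
#> celltyper_model: 2 cell types over 1556 genes
#> rmtl_model: 2 tasks, 1556 features (logistic loss, shared_offset regularizer)
#>   lambda1 = 0.01, lambda2 = 0.01; 26 iterations (converged); objective 0.0130655

pred <- predict(fit, sp$test$expr)
mean(pred == sp$test$labels)
#> [1] 1
round(rbind(recall    = class_metrics(sp$test$labels, pred)$recall,
            precision = class_metrics(sp$test$labels, pred)$precision), 3)
#>           group1 group2
#> recall         1      1
#> precision      1      1
```

The preprocessing kept all 500 cells (every simulated cell detects more than
1,000 genes) and 1,556 of 2,000 genes; the jointly trained two-task model
converges in 26 FISTA iterations and labels every held-out cell correctly —
at this DE strength the groups are linearly separable. Lower `de_facLoc`
toward its default 0.1 to make the problem hard, or set `de_prob = 0` for a
label-free negative control.

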