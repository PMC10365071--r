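# unbgcn

Cortical-atrophy biomarkers and population-graph classification for
early Alzheimer's disease (AD) research.

`unbgcn` is for neuroimaging researchers working with vertex-wise
cortical-thickness tables (e.g. FreeSurfer output registered to a common
surface, parcellated with the left-hemisphere Desikan–Killiany atlas).
It implements:

* a **univariate neurodegeneration biomarker (UNB)** per region of
  interest — a similarity score between an individual's vertex-wise
  atrophy pattern and the AD-group atrophy pattern;
* a **semi-supervised graph convolutional network (GCN)** with a
  dot-product **attention module**, classifying subjects on a
  phenotype-similarity population graph and ranking ROIs by learned
  attention weight;
* a **longitudinal evaluation suite**: minimum sample sizes, change
  rates, paired effect sizes, Pearson correlations, rank-based ROC/AUC
  with bootstrap confidence intervals;
* a **synthetic cohort generator** with planted atrophy effects, so the
  whole pipeline is testable without clinical data.

## The model in brief

For ROI $k$ with vertices $i = 1,\dots,m_k$, the biomarker is

$$ \mathrm{UNB}_k = \frac{1}{100}\sum_{i=1}^{m_k} Z_{sk_i}\, Z_{k_i}, $$

where $Z_{k_i}$ is the individual's atrophy z-score at vertex $i$
(thickness standardized against a cognitively-unimpaired reference after
age/gender adjustment, t-scores mapped to z through the exact quantile
transform) and $Z_{sk_i}$ is the AD-group atrophy z-score (vertex-wise
two-sample t between AD and CU, likewise mapped to z). Concordant
thinning at the same vertices makes the score large, so **greater UNB =
atrophy topography closer to AD**.

The classifier operates on a graph $G = \{V, E, W\}$ whose nodes carry
the 34-dimensional UNB vectors and whose edge weights count matching
phenotypes, $W(m,n) = \sum_l \alpha(M_l(m), M_l(n))$ — Kronecker delta
for gender, a strict unit step $1[|a-b| < \theta]$ (default
$\theta = 2$) for age and APOE $\varepsilon4$ count. Each layer applies
$H^{(k+1)} = \mathrm{ReLU}(S\,H^{(k)}\Theta^{(k)})$ with
$S = \tilde D^{-1/2}(W+I)\tilde D^{-1/2}$; an attention map
$A = \mathrm{softmax}(\mathrm{Linear}(XX^\top))$ refines the inputs as
$Z = X \odot A$. Training is transductive: loss on labeled nodes only.
The minimum sample size for a longitudinal biomarker is
$N = C\,\sigma^2/(m-b)^2$.

## Worked example

```r
library(unbgcn)

## 1. a synthetic three-group cohort at the default study conditions
coh  <- generate_cohort(cohort_config(seed = 42))
pipe <- unb_pipeline(coh$thickness, coh$phenotypes, coh$labels, atlas = TRUE)
round(tapply(rowSums(pipe$unb), coh$labels, mean), 2)
#>    AD   MCI    CU
#> 67.78 31.37  0.00
```

The per-group mean of the total UNB orders AD > MCI > CU: the planted
atrophy (0.30 mm in AD, 0.15 mm in MCI on 30% of ROIs) is recovered by
the biomarker, and the CU group centres at 0 by construction.

```r
## 2. longitudinal statistics over 24 months
fu <- unb_matrix(adjust_glm(coh$thickness_followup, coh$phenotypes,
                            fit_subjects = subjects(pipe$cu_reference)),
                 pipe$group_pattern, pipe$cu_reference)
tb <- rowSums(pipe$unb); tf <- rowSums(fu)[names(tb)]
ad <- names(coh$labels)[coh$labels == "AD"]
paired_test(tb[ad], tf[ad])[c("p_value", "effect_size")]
#> $p_value     2.17e-10
#> $effect_size 1.34
min_sample_size(tb[ad], tf[ad])$n
#> [1] 5
```

AD subjects' total UNB rises significantly over 24 months (paired
Cohen's d = 1.34), and the minimum sample size needed to detect that
change is smallest for AD (5 here vs. 33 for MCI and 35 for CU in this
cohort) — the more sensitive the biomarker, the fewer subjects a trial
needs. The AD-vs-CU ROC of the total UNB gives AUC 1.000 at these
planted effect sizes (`roc_auc(...)`).

```r
## 3. semi-supervised classification on a planted population graph
g <- planted_feature_graph(50, 5, seed = 1)   # 100 nodes, separation 5
m <- train_gcn(g, model_config(seed = 1))     # K = 3, dropout 0.3, 200 epochs
mean(predict_gcn(g, m)$labels == g$labels[g$test_mask])
#> [1] 1

## 4. attention-based ROI ranking on the cohort (train on all labeled nodes)
ids  <- names(coh$labels)[coh$labels %in% c("AD", "CU")]
phen <- coh$phenotypes[match(ids, coh$phenotypes$subject), ]
gful <- population_graph(pipe$unb[ids, ], build_adjacency(phen),
                         droplevels(coh$labels[ids]),
                         train_mask = rep(TRUE, length(ids)),
                         test_mask  = rep(FALSE, length(ids)))
m_cohort <- train_gcn(gful, model_config(seed = 1))
rank <- rank_roi_attention(m_cohort, roi_names = colnames(pipe$unb))
head(rank, 2)
#>               roi raw_weight normalized_weight displayed
#> 1 parsopercularis      0.750             0.750      TRUE
#> 2   parsorbitalis      0.236             0.236      TRUE
```

Both top-ranked ROIs are members of the cohort's planted affected set;
ROIs with normalized weight below 0.05 are flagged `displayed = FALSE`
rather than dropped.

A command-line wrapper ships in `inst/cli/unbgcn` with subcommands
`simulate`, `unb`, `graph`, `train`, `evaluate`, `attention`, `stats`
and `run` (the full pipeline); see `?unbgcn_cli`.

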