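# sfstrat

Similarity-stratified benchmarking of protein–ligand binding-affinity
scoring functions, for computational chemists and method developers who
want to know *how much* of a scoring function's performance comes from
training complexes similar to the test set.

A scoring function (SF) predicts the binding affinity of a protein–ligand
complex (in pKd/pKi units, the −log10 of the molar dissociation or
inhibition constant) from structural descriptors. `sfstrat` stratifies
the training set by its similarity to the test set and re-calibrates both
classical linear SFs and their machine-learning counterparts on every
stratum, exposing learning curves, crossing points and the sharp
performance leap driven by near-duplicate training complexes.

## The core constructions

Given the full training set OT, the test set TS and a similarity
s(p, q) between training complex p and test complex q, the
**dissimilar-first** nested training set at cutoff c is

    NT_ds(c) = { p ∈ OT : s(p, q) ≤ c for every q ∈ TS }

and the **similar-first** set NT_sd(c) = { p : s(p, q) > c for some q }
is its complement. For pocket-topology *dissimilarities* d(p, q) the
inequalities flip (keep p with d(p, q) ≥ c for all q). Sweeping c over a
schedule (protein structure 0.40→1.00 step 0.01; ligand-fingerprint
Tanimoto 0.50→1.00 step 0.01; pocket city-block 10.0→0.0 step 0.2)
yields nested families on which eight SFs are re-trained:

* `MLR::Xscore` (consensus of three OLS fits), `MLR::Vina` (five terms
  normalized by 1 + w_rot·Nrot with the rotor weight fixed),
  `MLR::Cyscore` — the classical trio;
* `RF::Xscore`, `RF::Vina`, `RF::Cyscore`, `RF::XVC`, `XGB::XVC` —
  random-forest and gradient-boosted counterparts on the *same*
  descriptors (XVC = the 16-descriptor hybrid).

Scoring power is Rp (Pearson), Rs (Spearman) and RMSE of predicted
versus measured affinity on the fixed test set. The tree ensembles are
implemented inside the package in C++ (no RF/boosting package exists in
the target environment); OLS fits are verified against a
normal-equations oracle.

## Worked example

Everything below is synthetic and self-contained (no downloads): the
generator plants a known affinity law over latent protein families,
including a 25% near-duplicate band above similarity 0.99.

```r
library(sfstrat)

bench <- generate_benchmark(
  synth_config(n_train = 400, n_test = 50, n_clusters = 12, seed = 42))

fam <- build_family(bench$protein, cutoff_schedule(0.40, 1.00, 0.10), "ds")
family_sizes(fam)
#>   cutoff n_train
#> 1    0.4      69
#> 2    0.5     141
#> ...
#> 7    1.0     400

curves <- sweep_scoring(
  list(sf_spec("MLR::Xscore"), sf_spec("RF::XVC", hyperparams = list(ntree = 200))),
  fam, bench$train_features, bench$train_affinities,
  bench$test_features, bench$test_affinities, seed = 42)
dplyr::select(curves, sf_name, cutoff, n_train, rp, rmse)
#>    sf_name     cutoff n_train    rp  rmse
#>  1 MLR::Xscore    0.4      69 0.472 0.913
#>  7 MLR::Xscore    1.0     400 0.493 0.917
#>  8 RF::XVC        0.4      69 0.503 0.894
#> 14 RF::XVC        1.0     400 0.876 0.510
```

Even at the lowest cutoff — training only on complexes dissimilar to
every test complex — the hybrid forest already outscores the classical
consensus (Rp 0.503 vs 0.472), and it keeps learning as similar
complexes enter, while the classical curve barely moves (0.472 to
0.493 across the whole sweep):

```r
find_crossing(curves, "RF::XVC", "MLR::Xscore", "rp")
#>   sf_a    sf_b        metric cutoff n_train sustained
#> 1 RF::XVC MLR::Xscore rp        0.4      69 TRUE

leap_deltas(curves[curves$sf_name == "RF::XVC", ], "rp")
#>   from  to delta
#> 6  0.9 1.0 0.207   # the sharp leap: the near-duplicate band enters
```

The largest per-step gain (+0.207 Rp) occurs on the final increment,
where the near-duplicate training complexes (similarity > 0.99 to some
test complex) join the training set. `autoplot(curves, "rp")` draws the
curves; `run_pipeline()` drives the whole analysis (stratify → sweep →
crossings → report, with a manifest) from one JSON or list config, and
`inst/cli/sfstrat.R` is a thin command-line wrapper around it.

Real data enter through plain tabular dialects: `read_feature_table()`
(CSV/TSV), `read_pdbbind_index()` (PDBbind-style index files) and
`read_similarity_matrix()` (labeled dense matrices, validated against
their declared kind).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the package's main computation from scratch against the
installed package: it generates a synthetic benchmark from the given
seed, builds nested families on all three similarity channels in both
sweep directions, re-calibrates six scoring functions on every nested
set, detects crossings and leaps, writes all artifacts, and emits the
results JSON.

See the methods vignette (`vignettes/similarity-stratification.Rmd`) for
the model, the synthetic-data design and its rationale, numerical
choices, and known limitations.
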