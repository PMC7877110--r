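# dicercleave

Structure-aware prediction of human Dicer cleavage sites on pre-miRNA
arms.

Pre-miRNAs are ~60–80 nt hairpins that Dicer cuts at a defined scissile
bond on each arm; the cut position fixes the mature miRNA's seed
sequence. `dicercleave` treats cleavage-site recognition as binary
classification of 14-nt windows: the *cleavage pattern* centred on the
bond (7 nt on each side) versus a *non-cleavage pattern* whose centre is
6 nt away, toward the arm's free terminus. Each window is paired with
its structure-derived complementary strand (unpaired positions written
as `O`), and encoded as

* 14 **relational features** `p1 … p14` — the categorical pair
  `(window[i], complement[i])` over `{A,C,G,U} × {A,C,G,U,O}`, and
* 1 **class feature** — the pattern's cluster id under affinity
  propagation on pairwise similarities
  `s(i,j) = −D_similar(i,j)`, where
  `D_similar(E,F) = D_edit(E1,F1) + D_edit(E2,F2)` sums the Levenshtein
  distances between windows and between complementary strands; test
  samples inherit the nearest exemplar's id.

A leaf-wise gradient-boosted tree ensemble (native categorical splits,
hyperparameters from an exhaustive grid search with stratified
cross-validation) classifies the windows, and a repeated random-split
protocol reports mean sensitivity, specificity, accuracy and Matthews
correlation coefficient, with splits drawn over pre-miRNA ids so sibling
windows never straddle train and test.

The package reads FASTA, Vienna dot-bracket and mfold/quickfold CT
files plus a per-arm cleavage-annotation TSV (`id`, `arm`,
`cleavage_pos`), and ships a synthetic hairpin generator with
ground-truth structure and a plantable cleavage motif so the entire
pipeline is testable without external data or folding tools. It is for
researchers studying miRNA biogenesis who want a transparent,
reproducible cleavage-site classifier they can retrain on their own
structure-annotated data.

## Worked example

```r
library(dicercleave)

editDistance("UAUAGUUUUAGGGU", "UAUGGUUUAGAGUU")
#> [1] 4

# synthetic hairpins with a cleavage motif planted at 90% strength
spec <- hairpinSpec(motif = "UGGC", motifStrength = 0.9)
ds <- generateDataset(130, spec, seed = 42)
ps <- buildPatternSet(ds$sequences, ds$pairTables, ds$annotations,
                      arm = "5p")
ps
#> PatternSet with 260 patterns (130 cleavage, 130 non-cleavage)
#>   synth-mir-0001 5p cleavage CCGCGCUGGCGAGC | GGCGCGUUGCCUCG
#>   synth-mir-0001 5p non_cleavage AUGAAACCGCGCUG | UACUUUGGCGCGUU
#>   synth-mir-0002 5p cleavage GGACCAUGGCGAUG | CCUOOCGGUUCUAC
#>   ...

report <- runExperiment(ps, nRepeats = 3,
                        trainPos = 100, trainNeg = 100,
                        testPos = 25, testNeg = 25, seed = 7,
                        grid = data.frame(max_depth = 10L,
                                          learning_rate = 0.1,
                                          num_leaves = 200L))
report
#> ExperimentReport: 3 repeats (train 100+100, test 25+25)
#>   mean Sn=0.973 Sp=0.960 Acc=0.967 MCC=0.934

head(featureImportance(report$importance, type = "gain"), 4)
#>    feature      score
#> 13     p13 0.60214330
#> 7       p7 0.19590120
#> 8       p8 0.06292000
#> 14     p14 0.05026926
```

The per-repeat metrics mean: of the 50 test windows in each repeat,
~97% are called correctly, and an MCC of 0.93 indicates the calls are
far from chance on this balanced test set. The importance ranking shows
where the model looks: the motif is planted at window offsets 7–10 of
cleavage windows, and because the non-cleavage window is the same
sequence shifted 6 nt, the motif's first letters also surface at
offsets 13–14 there — so positions 7 and 13 carry the bulk of the
discriminative gain, exactly the planted locations.

`complementOfWindow()`, `extractCleavagePattern()` /
`extractNonCleavagePattern()`, `buildSimilarityMatrix()`,
`affinityPropagation()`, `classRatioSummary()`, `gridSearchTrain()` and
`predictCleavage()` expose the individual stages; see the methods
vignette (`vignettes/dicercleave-methods.Rmd`) for the model,
conventions and design choices. A thin command-line front end over
these functions is at `inst/cli/dicercleave.R`
(`simulate | convert | extract | cluster | evaluate`).

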