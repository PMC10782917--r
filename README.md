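# sgcae — spatial-domain identification with a symmetric graph convolutional auto-encoder

`sgcae` identifies spatial domains (cortical layers, laminae, anatomical
regions) in spatial transcriptomic data. Each tissue spot carries a
gene-expression profile and a 2-D coordinate; the package embeds spots with
a two-layer graph convolutional auto-encoder that smooths over **expression
similarity** and **spatial proximity** simultaneously, then clusters the
embedding and spatially refines the labels. It is written for analysts of
spotted and high-resolution platforms (Visium-style arrays, grid-sampled
and binned high-resolution data) who need domain calls that scale to large
spot counts on modest hardware.

## The model

The auto-encoder input is the matrix $X$ of the top $D = 50$ principal
components of the normalized expression. For each mini-batch of $n$ spots
(default $n = 2000$), two Gaussian-kernel adjacencies are built:

$$w_e(u,v) = \exp\!\left(-\frac{\lVert\vec x_u - \vec x_v\rVert^2}{2 l_e^2}\right),
\qquad
w_p(u,v) = \exp\!\left(-\frac{\lVert\vec p_u - \vec p_v\rVert^2}{2 l_p^2}\right),$$

with each bandwidth solved from $-d_\tau^2 / (2l^2) = m$, where $d_\tau$ is
the $\tau = 0.07$ off-diagonal distance quantile of the batch and $m$ is the
largest integer with $\exp(m) = 0$ in the working precision. Kernel entries
at distance $\ge d_\tau$ are then *exactly* zero, so every batch has the
same expected neighbour fraction $\tau$ — the calibration that makes random
mini-batches work and keeps memory at $O(n^2)$ regardless of the total spot
count $N$.

The encoder smooths, $H^{(k)} = \mathrm{ELU}(W H^{(k-1)} B^{(k)})$
(expression layer, then spatial layer); the decoder sharpens with
$\hat W = 3I - W$ and tied transposed weights
$\hat B^{(k)} = (B^{(k)})^\top$, reconstructing $X$. The whole model has
$2D^2$ trainable scalars, trained by SGD (learning rate 0.2, dropping to 0.1
for the last 20 of 100 epochs) on the reconstruction error
$\lVert X - \hat X\rVert_2$. Domains come from `mclust` Gaussian-mixture
clustering of the embedding when the domain count is known, otherwise
Louvain at resolution 1.2; a majority vote over each spot's 6 nearest
spatial neighbours refines the labels. One-vs-rest Wilcoxon tests with
per-domain Benjamini–Hochberg correction produce marker tables.

## Worked example

```r
library(sgcae)

ds  <- generate_layered_dataset(synth_config(seed = 1))  # 3000 spots, 5 bands
run <- run_pipeline(ds$counts, ds$coords, n_domains = 5,
                    epochs = 30, seed = 1)

head(run$fit$history[c("epoch", "lr", "mean_loss")], 3)
#>   epoch  lr mean_loss
#> 1     1 0.2  166.9330
#> 2     2 0.2  162.7758
#> 3     3 0.2  159.3055

score_ari(run$labels, ds$truth)          # clustering vs simulated truth
#> [1] 1
score_ari(run$labels_refined, ds$truth)  # after spatial refinement
#> [1] 1

subset(run$deg, domain == 1)[1:3, c("gene_id", "log2_fc", "p_adj")]
#>   gene_id  log2_fc p_adj
#> 1 gene011 2.164323     0
#> 2 gene012 2.166907     0
#> 3 gene013 2.141964     0
```

The history shows the mean per-epoch Frobenius reconstruction loss falling
(166.9 at epoch 1 to 135.0 at epoch 30 on this fixture). The two ARI values
compare inferred domains with the simulator's ground truth — 1.0 means the
five bands are recovered exactly (cluster numbering is arbitrary, so a
domain's top markers may be another band's planted genes). The marker table
lists each domain's genes sorted by adjusted p, with log2 fold changes on
the back-transformed scale.

A thin command-line wrapper with `simulate` and `run` subcommands is
installed at `inst/cli/sgcae.R`:

```sh
Rscript inst/cli/sgcae.R simulate --out data --n-spots 3000 --seed 7
Rscript inst/cli/sgcae.R run --input data --out results --n-domains 5 --seed 7
```

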