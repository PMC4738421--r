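Q: 10
dt: 1.0
n_steps: 100000
initial: uniform
enabled:
- ff_metabolic
- ff_protein
- mb
- repair
- ec
- ed
seed: 1
record_every: 100
record_snapshots: no
params:
  gamma: 1.0
  ff1: 2.0
  ff2: 3.0
  f_rd: 0.29999999999999999
  ffm:
    rho0: 0.05
    tau: 50000.0
    direction: decay
  ffp:
    rho0: 0.05
    tau: 50000.0
  mb:
    rho0: 0.01
    tau: 50000.0
    direction: growth
  rep:
    rho0: 0.01
    tau: 50000.0
    direction: decay
  ec:
    rho0: 0.05
    tau: 50000.0
    direction: growth
  ed:
    rho0: 0.10000000000000001
    tau: 50000.0
    direction: growth
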