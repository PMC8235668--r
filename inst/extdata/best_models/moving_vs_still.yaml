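# Published best configuration: moving vs. still node (values as printed).
node: moving_vs_still
n_dense_layers: 1
units: [42]
activations: [tanh]
use_conv: false
use_pooling: false
use_lstm: false
learning_rate: 0.01
optimizer: sgd
batch_size: 48
window_length: 32
channels: [P3, P4, P6, P8, P10, P12, P13, A0, A2]
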