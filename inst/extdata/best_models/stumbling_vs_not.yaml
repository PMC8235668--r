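# Published best configuration: stumbling vs. not-stumbling node (values as
# printed; note the conv window exceeds the window length).
node: stumbling_vs_not
n_dense_layers: 11
units: [26, 54, 16, 38, 46, 54, 18, 38, 36, 54, 1]
activations: [tanh, selu, selu, selu, selu, tanh, selu, selu, selu, tanh, selu]
use_conv: true
conv_filters: 21
conv_window: 10
conv_activation: selu
use_pooling: false
use_lstm: false
learning_rate: 0.01
optimizer: sgd
batch_size: 21
window_length: 4
channels: [P0, P1, P4, P7, P10, P11, P12, P14, A1]
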