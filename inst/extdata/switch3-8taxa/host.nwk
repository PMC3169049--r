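(((host03:0.4944254201,host05:0.4944254201):0.2029594179,(host01:0.2584132576,host07:0.2584132576):0.4389715804):0.382388608,(((host04:0.02103176742,host08:0.02103176742):0.2874836483,host06:0.3085154158):0.3085463439,host02:0.6170617596):0.4627116864);
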