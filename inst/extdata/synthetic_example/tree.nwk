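(((otu0023:1.17611085,(otu0020:0.1861708685,otu0028:0.1861708685):0.9899399815):0.5499996645,((otu0011:0.1744659561,otu0021:0.1744659561):1.277200906,(((((otu0029:0.2139602031,(otu0003:0.05473958903,otu0015:0.05473958903):0.1592206141):0.1575097177,otu0009:0.3714699208):0.2990003564,(otu0016:0.6008019297,((otu0001:0.1401763217,(otu0024:0.09834063111,(otu0025:0.04287256865,otu0004:0.04287256865):0.05546806246):0.04183569056):0.4318919448,otu0022:0.5720682664):0.02873366326):0.06966834747):0.04064335219,otu0019:0.7111136294):0.6162082,(((otu0013:0.7918934244,(otu0027:0.6309640859,otu0018:0.6309640859):0.1609293385):0.3069385764,(((otu0030:0.3413827972,otu0026:0.3413827972):0.1248669703,((otu0008:0.07881301905,otu0005:0.07881301905):0.2180342206,otu0012:0.2968472397):0.1694025279):0.3634150901,(otu0014:0.8266130444,otu0007:0.8266130444):0.003051813278):0.2691671431):0.0717567232,(otu0006:0.7305447369,(otu0017:0.5188185268,otu0010:0.5188185268):0.2117262101):0.4400439871):0.1567331054):0.1243450324):0.2744436526):0.6257278449,otu0002:2.351838359);
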