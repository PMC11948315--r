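model,experiment,af,count
VGG16,Exp1,ReLU,0
VGG16,Exp1,ELU,1
VGG16,Exp1,SELU,1
VGG16,Exp1,Mish,1
VGG16,Exp1,SiLU,0
VGG16,Exp1,GELU,0
VGG16,Exp2,ReLU,1
VGG16,Exp2,ELU,1
VGG16,Exp2,SELU,0
VGG16,Exp2,Mish,1
VGG16,Exp2,SiLU,0
VGG16,Exp2,GELU,0
VGG16,Exp3,ReLU,0
VGG16,Exp3,ELU,1
VGG16,Exp3,SELU,1
VGG16,Exp3,Mish,1
VGG16,Exp3,SiLU,0
VGG16,Exp3,GELU,1
DenseNet121,Exp1,ReLU,0
DenseNet121,Exp1,ELU,3
DenseNet121,Exp1,SELU,6
DenseNet121,Exp1,Mish,2
DenseNet121,Exp1,SiLU,3
DenseNet121,Exp1,GELU,2
DenseNet121,Exp2,ReLU,0
DenseNet121,Exp2,ELU,3
DenseNet121,Exp2,SELU,4
DenseNet121,Exp2,Mish,3
DenseNet121,Exp2,SiLU,2
DenseNet121,Exp2,GELU,1
DenseNet121,Exp3,ReLU,1
DenseNet121,Exp3,ELU,3
DenseNet121,Exp3,SELU,6
DenseNet121,Exp3,Mish,1
DenseNet121,Exp3,SiLU,2
DenseNet121,Exp3,GELU,1
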