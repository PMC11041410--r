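paragraph_group,participant_group,generator_group,truth,n_pred_authentic,n_pred_fake
trained_paragraph,model_trained_participant,model_naive_generator,fake,5,17
trained_paragraph,model_naive_participant,authentic,authentic,25,1
trained_paragraph,model_naive_participant,model_trained_generator,fake,3,10
trained_paragraph,model_naive_participant,model_naive_generator,fake,1,7
trained_paragraph,pregenerated_tts,model_trained_generator,fake,17,31
trained_paragraph,pregenerated_tts,model_naive_generator,fake,0,4
naive_paragraph,model_trained_participant,authentic,authentic,19,8
naive_paragraph,model_trained_participant,model_trained_generator,fake,7,29
naive_paragraph,model_trained_participant,model_naive_generator,fake,0,14
naive_paragraph,model_naive_participant,authentic,authentic,16,6
naive_paragraph,model_naive_participant,model_trained_generator,fake,1,7
naive_paragraph,model_naive_participant,model_naive_generator,fake,1,2
naive_paragraph,pregenerated_tts,model_trained_generator,fake,3,21
naive_paragraph,pregenerated_tts,model_naive_generator,fake,0,2
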